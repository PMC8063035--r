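# Estimation of the per-cell zero-inflated Poisson background distribution.
#
# If a cell holds N_bg background genes whose non-suppressed counts follow
# Poisson(lambda), the expected frequency of count value y is
# n_y ~ N_bg' e^{-lambda} lambda^y / y!, so w_y = log(n_y) + log(y!) is linear
# in y with slope log(lambda) and intercept log(N_bg') - lambda. Only the
# low-count bins y = 1..yMax enter the regression: higher bins are
# increasingly contaminated by active-phase observations, and the regression
# is made robust to the contamination that remains inside the window.

#' Log-frequency points for the background regression
#'
#' Tabulates the count values `y = 1..yMax` of one cell and returns, for every
#' value observed at least once, the regression ordinate
#' `w_y = log(n_y) + log(y!)`, which is linear in `y` under a Poisson
#' background with slope `log(lambda)`.
#'
#' @param y integer vector of one cell's counts.
#' @param yMax upper count bound of the regression window (>= 2).
#' @return data.frame with columns `y`, `n` (frequency) and `w`.
#' @examples
#' logFreqPoints(c(rep(1, 100), rep(2, 50), rep(3, 17), rep(0, 500)))
#' @export
logFreqPoints <- function(y, yMax = 10L) {
  if (yMax < 2L) stop("yMax must be at least 2")
  tab <- tabulate(y[y >= 1L & y <= yMax], nbins = yMax)
  keep <- which(tab >= 1L)
  if (length(keep) < 2L)
    stop("insufficient low-count support: fewer than 2 distinct count values in 1..yMax")
  data.frame(y = keep, n = tab[keep], w = log(tab[keep]) + lgamma(keep + 1))
}

#' ZIP background parameters of one cell
#'
#' Fits `w_y = c + y log(lambda)` over the low-count bins by Tukey-bisquare
#' iteratively reweighted least squares (base weights `n_y`, since
#' `Var(log n_y) ~ 1/n_y`), initialized from the two lowest bins. The implied
#' number of non-suppressed background genes is `exp(c + lambda)`; the
#' zero-inflation mass `p0` is then read off the excess of observed zeros over
#' the Poisson prediction, with one fixed-point pass to express the excess
#' relative to the full background population `N_bg / (1 - p0)` (the ZIP is
#' parameterized so that `P(Y = 0) = p0 + (1 - p0) e^{-lambda}`).
#'
#' With `robustIters = 0` the fit degenerates to plain weighted least squares,
#' which is sensitive to active-phase contamination inside the window.
#'
#' @inheritParams logFreqPoints
#' @param robustIters IRLS rounds (default 20).
#' @return list with `p0`, `lambda`, `nBgHat` and the fitted `points` table.
#' @examples
#' set.seed(1)
#' y <- ifelse(rbinom(5000, 1, 0.3) == 1, 0L, rpois(5000, 1))
#' estimateZIP(y)[c("p0", "lambda")]
#' @export
estimateZIP <- function(y, yMax = 10L, robustIters = 20L) {
  pts <- logFreqPoints(y, yMax)
  G <- length(y)
  cf <- .robustLine(pts$y, pts$w, pts$n, robustIters)
  if (any(!is.finite(cf))) {
    # degenerate regression: ratio estimator from the first two bins,
    # n_2 / n_1 = lambda / 2 under the Poisson background
    n1 <- pts$n[pts$y == 1L]; n2 <- pts$n[pts$y == 2L]
    if (!length(n1) || !length(n2))
      stop("insufficient low-count support: background regression degenerate")
    lam <- 2 * n2 / n1
    cf <- c(log(n1) - log(lam), log(lam))  # from w_1 = c + log(lambda)
  }
  lam <- exp(cf[2L])
  nBg <- min(max(exp(cf[1L] + lam), 0), G)
  n0 <- sum(y == 0L)
  p0 <- max(0, (n0 - nBg * exp(-lam)) / G)
  nTot <- nBg / (1 - min(p0, 0.999))
  p0 <- min(max(0, (n0 - nBg * exp(-lam)) / nTot), 0.999)
  list(p0 = unname(p0), lambda = unname(lam), nBgHat = unname(nBg),
       points = pts)
}

#' ZIP background parameters for every cell
#'
#' Runs [estimateZIP()] on each column of the count matrix. Cells for which
#' the estimate fails (for example all-zero cells, or cells without at least
#' two populated low-count bins) receive the median parameters of the
#' successful cells and are flagged.
#'
#' @param x count container accepted by the package.
#' @inheritParams estimateZIP
#' @param verbose emit one line per flagged cell.
#' @return a [BackgroundParams-class].
#' @export
estimateBackground <- function(x, yMax = 10L, robustIters = 20L,
                               verbose = FALSE) {
  m <- .asCounts(x)
  n <- ncol(m)
  p0 <- lam <- nBg <- rep(NA_real_, n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    est <- tryCatch(estimateZIP(m[, i], yMax, robustIters),
                    error = function(e) NULL)
    if (!is.null(est)) {
      p0[i] <- est$p0; lam[i] <- est$lambda; nBg[i] <- est$nBgHat
      ok[i] <- TRUE
    }
  }
  if (!any(ok)) stop("background estimation failed for every cell")
  if (any(!ok)) {
    p0[!ok] <- stats::median(p0[ok])
    lam[!ok] <- stats::median(lam[ok])
    nBg[!ok] <- stats::median(nBg[ok])
    for (i in which(!ok))
      .msg(verbose, "cell %s: background estimation failed, cohort median imputed",
           colnames(m)[i])
  }
  methods::new("BackgroundParams",
    cellIds = colnames(m), p0 = p0, lambda = lam, nBgHat = nBg,
    flagged = !ok, librarySize = unname(colSums(m)),
    yMax = as.integer(yMax))
}
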
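# Normalization factors: active-phase residuals, per-cell robust spline bias
# curves, log S evaluation, the reference-cell identifiability constraint,
# and application as offset or adjusted counts.

#' Active-phase residuals
#'
#' For every gene-cell pair called active (`Zpost > threshold`) with a
#' non-zero count and an estimable gene, the residual
#' `eps = log Y - mu_hat[g]`, whose expectation is the log technical bias
#' `log S`. The fitting abscissa for the bias curves is the gene's mean log
#' expression `mu_hat`.
#'
#' @param x count container accepted by the package.
#' @param fit a [TwoPhaseFit-class].
#' @param threshold posterior activation cutoff (default 0.99).
#' @return data.frame with columns `gene_id`, `cell_id`, `mu` (abscissa),
#'   `log_y`, `eps`.
#' @export
computeResiduals <- function(x, fit, threshold = 0.99) {
  m <- .asCounts(x)
  stopifnot(identical(rownames(m), fit@geneIds),
            identical(colnames(m), fit@cellIds))
  act <- phaseCall(fit, threshold) & m >= 1L & fit@estimable
  idx <- which(act, arr.ind = TRUE)
  data.frame(
    gene_id = fit@geneIds[idx[, 1L]],
    cell_id = fit@cellIds[idx[, 2L]],
    mu = fit@mu[idx[, 1L]],
    log_y = log(m[idx]),
    eps = log(m[idx]) - fit@mu[idx[, 1L]],
    stringsAsFactors = FALSE
  )
}

# -- curve objects ----------------------------------------------------------
# A curve is a list: type "spline" (natural cubic basis: knots, boundary,
# coef incl. intercept), "constant" (value), or "cohort" (pointwise-median
# grid, linearly interpolated). All types extrapolate as a constant outside
# the fitted abscissa range xr.

#' Evaluate a per-cell bias curve
#'
#' @param curve a curve object from [fitCellCurve()] or [biasCurves()].
#' @param x abscissae (mean log expression or log count).
#' @return numeric values of the curve, constant outside its fitted range.
#' @export
evalCurve <- function(curve, x) {
  xc <- pmin(pmax(x, curve$xr[1L]), curve$xr[2L])
  switch(curve$type,
    constant = rep(curve$value, length(x)),
    cohort = stats::approx(curve$gridX, curve$gridY, xout = xc, rule = 2)$y,
    spline = {
      B <- splines::ns(xc, knots = curve$knots,
                       Boundary.knots = curve$boundary)
      drop(cbind(1, B) %*% curve$coef)
    },
    stop("unknown curve type")
  )
}

#' Robust smooth bias curve for one cell
#'
#' Natural cubic regression spline of the cell's residuals on mean log
#' expression with `df` degrees of freedom (interior knots at quantiles),
#' fitted by Tukey-bisquare IRLS (`robustIters` rounds, default 3) so that
#' outlying residuals - including genuinely differentially expressed genes -
#' do not bend the technical-bias estimate. Beyond the fitted abscissa range
#' the curve extrapolates as a constant.
#'
#' @param res residual table from [computeResiduals()].
#' @param cell cell id to fit.
#' @param df spline degrees of freedom (default 5); reduced with a warning if
#'   it reaches the number of points.
#' @param robustIters bisquare rounds.
#' @param minCurvePoints minimum residuals for a spline fit (default 50);
#'   below it the curve falls back to the robust mean (median) of the cell's
#'   residuals, and with fewer than `minConstPoints` residuals to `NULL` (the
#'   caller substitutes the cohort-median curve).
#' @param minConstPoints minimum residuals for the constant fallback.
#' @return a curve object (see [evalCurve()]), or `NULL` when the cell has too
#'   few residuals even for a constant.
#' @export
fitCellCurve <- function(res, cell, df = 5L, robustIters = 3L,
                         minCurvePoints = 50L, minConstPoints = 10L) {
  d <- res[res$cell_id == cell, , drop = FALSE]
  n <- nrow(d)
  if (n < minConstPoints) return(NULL)
  xr <- range(d$mu)
  if (n < minCurvePoints || diff(xr) < 1e-8)
    return(list(type = "constant", value = stats::median(d$eps), xr = xr))
  if (df >= n) {
    warning(sprintf("cell %s: df reduced from %d to %d (only %d points)",
                    cell, df, n - 1L, n))
    df <- n - 1L
  }
  B <- splines::ns(d$mu, df = df)
  Xd <- cbind(1, B)
  fit <- stats::lm.fit(Xd, d$eps)
  for (k in seq_len(robustIters)) {
    r <- d$eps - drop(Xd %*% fit$coefficients)
    s <- stats::mad(r)
    if (s < 1e-10) break  # (near-)exact fit: nothing left to reweight
    u <- pmin(abs(r / (4.685 * s)), 1)
    fit <- stats::lm.wfit(Xd, d$eps, (1 - u^2)^2)
  }
  list(type = "spline", coef = unname(fit$coefficients),
       knots = as.numeric(attr(B, "knots")),
       boundary = as.numeric(attr(B, "Boundary.knots")), xr = xr)
}

.cohortMedianCurve <- function(curves, xr, gridN = 101L) {
  fitted <- Filter(function(cv) !is.null(cv) && cv$type != "cohort", curves)
  if (!length(fitted))
    return(list(type = "constant", value = 0, xr = xr))
  gx <- seq(xr[1L], xr[2L], length.out = gridN)
  vals <- vapply(fitted, evalCurve, numeric(gridN), x = gx)
  list(type = "cohort", gridX = gx,
       gridY = apply(as.matrix(vals), 1L, stats::median), xr = xr)
}

#' Evaluate log normalization factors from fitted curves
#'
#' Reads the log factor for every active gene-cell pair off the cell's bias
#' curve: at the gene's mean log expression (`mode = "at_mu"`, the default,
#' which gives every active observation of a gene in a cell the same factor)
#' or at the observed log count (`mode = "at_count"`, which tracks the
#' realized count but re-injects its Poisson noise into the factor - see the
#' methods vignette). Background entries, zero counts and unestimable genes
#' are masked (`NA`).
#'
#' @param curves named per-cell list of curve objects.
#' @param x count container accepted by the package.
#' @param active logical genes x cells activity matrix (from [phaseCall()]).
#' @param mode evaluation abscissa, `"at_count"` or `"at_mu"`.
#' @param fit the [TwoPhaseFit-class] (needed for `mu` and estimability).
#' @return an unscaled [NormFactorMatrix-class].
#' @export
evalLogS <- function(curves, x, active, mode = c("at_mu", "at_count"), fit) {
  mode <- match.arg(mode)
  m <- .asCounts(x)
  G <- nrow(m); n <- ncol(m)
  mask <- active & m >= 1L & fit@estimable
  lS <- matrix(NA_real_, G, n, dimnames = dimnames(m))
  for (i in seq_len(n)) {
    cv <- curves[[colnames(m)[i]]]
    rows <- which(mask[, i])
    if (!length(rows) || is.null(cv)) next
    ab <- if (mode == "at_count") log(m[rows, i]) else fit@mu[rows]
    lS[rows, i] <- evalCurve(cv, ab)
  }
  methods::new("NormFactorMatrix",
    geneIds = rownames(m), cellIds = colnames(m), logS = lS,
    curves = curves, referenceCell = colnames(m)[1L],
    nActive = as.integer(unname(colSums(mask))),
    curveFallback = vapply(colnames(m), function(cid) {
      cv <- curves[[cid]]
      if (is.null(cv)) "none" else cv$type
    }, character(1)),
    rescaled = FALSE)
}

#' Apply the reference-cell identifiability constraint
#'
#' Shifts every log factor by minus the log of the mean factor
#' `mean(exp(log S))` over the unmasked genes of the reference cell (the
#' median-depth cell), so that the average S in that cell is exactly 1.
#' Idempotent. If the reference cell has no unmasked entry, the unmasked cell
#' with library size closest to the median is used instead, with a warning.
#'
#' @param nf a [NormFactorMatrix-class].
#' @param ls a [LibrarySizes-class] for the same cells.
#' @return the rescaled [NormFactorMatrix-class].
#' @export
rescaleToReference <- function(nf, ls) {
  stopifnot(is(nf, "NormFactorMatrix"), is(ls, "LibrarySizes"))
  ref <- ls@referenceCell
  refCol <- match(ref, nf@cellIds)
  if (all(is.na(nf@logS[, refCol]))) {
    usable <- which(colSums(!is.na(nf@logS)) > 0L)
    if (!length(usable)) stop("all cells fully masked; nothing to rescale")
    Lu <- ls@L[nf@cellIds[usable]]
    pick <- usable[which.min(abs(Lu - stats::median(ls@L)))]
    warning(sprintf(
      "reference cell %s fully masked; using %s (library size nearest the median)",
      ref, nf@cellIds[pick]))
    refCol <- pick
    ref <- nf@cellIds[pick]
  }
  shift <- log(mean(exp(nf@logS[, refCol]), na.rm = TRUE))
  nf@logS <- nf@logS - shift
  for (nm in names(nf@curves)) {
    cv <- nf@curves[[nm]]
    if (is.null(cv)) next
    if (cv$type == "spline") cv$coef[1L] <- cv$coef[1L] - shift
    else if (cv$type == "constant") cv$value <- cv$value - shift
    else cv$gridY <- cv$gridY - shift
    nf@curves[[nm]] <- cv
  }
  nf@referenceCell <- ref
  nf@rescaled <- TRUE
  methods::validObject(nf)
  nf
}

#' Full normalization-factor estimation
#'
#' Pipeline from a fitted two-phase model to rescaled factors: active-phase
#' residuals, one robust spline curve per cell (with the fallback ladder:
#' spline, then the cell's median residual, then the cohort-median curve),
#' evaluation of log S, and the reference-cell constraint.
#'
#' @inheritParams computeResiduals
#' @inheritParams fitCellCurve
#' @inheritParams evalLogS
#' @param ls library sizes; computed from `x` when missing.
#' @param verbose report fallback cells.
#' @return a rescaled [NormFactorMatrix-class].
#' @export
estimateNormFactors <- function(x, fit, threshold = 0.99, df = 5L,
                                mode = c("at_mu", "at_count"),
                                robustIters = 3L, minCurvePoints = 50L,
                                minConstPoints = 10L, ls = NULL,
                                verbose = FALSE) {
  mode <- match.arg(mode)
  m <- .asCounts(x)
  ls <- ls %||% librarySizes(m)
  res <- computeResiduals(m, fit, threshold)
  curves <- lapply(colnames(m), function(cid)
    fitCellCurve(res, cid, df = df, robustIters = robustIters,
                 minCurvePoints = minCurvePoints,
                 minConstPoints = minConstPoints))
  names(curves) <- colnames(m)
  needCohort <- vapply(curves, is.null, logical(1))
  if (any(needCohort)) {
    xr <- range(res$mu)
    cohort <- .cohortMedianCurve(curves, xr)
    for (i in which(needCohort)) {
      .msg(verbose, "cell %s: too few active residuals, cohort-median curve used",
           colnames(m)[i])
      curves[[i]] <- cohort
    }
  }
  nf <- evalLogS(curves, m, phaseCall(fit, threshold), mode = mode, fit = fit)
  rescaleToReference(nf, ls)
}

#' Use the normalization factors
#'
#' `mode = "offset"` returns the masked log-factor matrix untouched, for use
#' as an offset in count models. `mode = "adjusted"` divides each unmasked
#' count by its factor (`Y / S`) and leaves masked (background) counts
#' unchanged; the returned matrix carries a `recommendedGenes` attribute with
#' the genes active in at least `minCellsActive` cells, the recommended filter
#' when adjusted values are used directly.
#'
#' @param x count container accepted by the package.
#' @param nf a [NormFactorMatrix-class].
#' @param mode `"offset"` or `"adjusted"`.
#' @param minCellsActive filter threshold for the recommended gene list.
#' @return a genes x cells matrix (log factors, or adjusted counts).
#' @export
applyNormFactors <- function(x, nf, mode = c("offset", "adjusted"),
                             minCellsActive = 3L) {
  mode <- match.arg(mode)
  m <- .asCounts(x)
  stopifnot(all(dim(m) == dim(nf@logS)))
  if (mode == "offset") return(nf@logS)
  adj <- ifelse(is.na(nf@logS), m, m / exp(ifelse(is.na(nf@logS), 0, nf@logS)))
  dimnames(adj) <- dimnames(m)
  attr(adj, "recommendedGenes") <- recommendedGenes(nf, minCellsActive)
  adj
}

#' Genes recommended for direct use of adjusted counts
#'
#' Genes with an unmasked (active) factor in at least `minCellsActive` cells.
#'
#' @param nf a [NormFactorMatrix-class].
#' @param minCellsActive minimum active cells (default 3).
#' @return character vector of gene ids.
#' @export
recommendedGenes <- function(nf, minCellsActive = 3L) {
  nf@geneIds[rowSums(!is.na(nf@logS)) >= minCellsActive]
}
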
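# Two-phase mixture model and its EM fit.
#
# Observed count Y_gi is a mixture over the latent phase Z_gi:
#   active (Z = 1):     Y | theta ~ Poisson(theta * S),  theta ~ LN(mu_g, sigma2_g)
#   background (Z = 0): Y ~ ZIP(p0_i, lambda_i)
# All logs are natural. The active-phase pmf (a Poisson-lognormal) has no
# closed form; it is integrated by Gauss-Hermite quadrature re-centred at the
# mode of the integrand, which keeps the nodes where the mass is for every
# count value (crucial for large y, where the Poisson kernel is much narrower
# than the lognormal prior).

.ghCache <- new.env(parent = emptyenv())

.ghNodes <- function(n) {
  key <- as.character(n)
  if (is.null(.ghCache[[key]]))
    .ghCache[[key]] <- pracma::gaussHermite(n)
  .ghCache[[key]]
}

# Vectorized Poisson-lognormal pmf over aligned vectors y, mu, s2, ls.
# With moments = TRUE also returns the posterior mean and second moment of
# the latent log concentration u given y (needed by the exact EM M-step).
.plnDensity <- function(y, mu, s2, ls, nNodes = 25L, newtonIters = 14L,
                        moments = FALSE) {
  gh <- .ghNodes(nNodes)
  # Newton for the mode of log[ Pois(y; e^{u+ls}) N(u; mu, s2) ] in u
  u <- mu
  pos <- which(y > 0)
  u[pos] <- log(y[pos]) - ls[pos]
  for (k in seq_len(newtonIters)) {
    eu <- exp(u + ls)
    step <- (y - eu - (u - mu) / s2) / (-eu - 1 / s2)
    u <- u - pmax(pmin(step, 2), -2)
  }
  sig <- 1 / sqrt(exp(u + ls) + 1 / s2)
  lgy <- lgamma(y + 1)
  lnorm <- -0.5 * log(2 * pi * s2)
  # node offsets enter as u_k = u + sqrt(2) sig x_k; posterior moments of u
  # follow from the node-weighted sums T_j = sum_k x_k^j f_k
  t0 <- 0; t1 <- 0; t2 <- 0
  for (k in seq_len(nNodes)) {
    uk <- u + sqrt(2) * sig * gh$x[k]
    lf <- y * (uk + ls) - exp(uk + ls) - lgy + lnorm - (uk - mu)^2 / (2 * s2)
    fk <- gh$w[k] * exp(gh$x[k]^2 + lf)
    t0 <- t0 + fk
    if (moments) {
      t1 <- t1 + gh$x[k] * fk
      t2 <- t2 + gh$x[k]^2 * fk
    }
  }
  p <- pmin(sqrt(2) * sig * t0, 1)
  if (!moments) return(p)
  safe <- pmax(t0, 1e-300)
  r1 <- t1 / safe
  r2 <- t2 / safe
  m1 <- u + sqrt(2) * sig * r1
  m2 <- u^2 + 2 * sqrt(2) * u * sig * r1 + 2 * sig^2 * r2
  list(p = p, m1 = m1, m2 = m2)
}

#' Active-phase count probability
#'
#' P(Y = y | active) for the Poisson-lognormal active phase: a Poisson count
#' whose rate is `exp(u + logS)` with `u ~ N(mu, sigma2)`, integrated over `u`
#' by mode-centred Gauss-Hermite quadrature with `nNodes` nodes. Arguments are
#' recycled to a common length.
#'
#' @param y non-negative integer count(s).
#' @param mu,sigma2 lognormal parameters of the expression concentration
#'   (natural log scale); `sigma2 > 0`.
#' @param logS log technical bias factor (0 for an unbiased measurement).
#' @param nNodes number of quadrature nodes (>= 5; default 25).
#' @return probabilities in [0, 1].
#' @examples
#' activeDensity(2, log(3), 1e-8)   # ~ dpois(2, 3)
#' activeDensity(0:5, 1, 0.5)
#' @export
activeDensity <- function(y, mu, sigma2, logS = 0, nNodes = 25L) {
  if (nNodes < 5L) stop("nNodes must be at least 5")
  n <- max(length(y), length(mu), length(sigma2), length(logS))
  y <- rep_len(y, n); mu <- rep_len(mu, n)
  sigma2 <- rep_len(sigma2, n); logS <- rep_len(logS, n)
  if (any(!is.finite(y)) || any(!is.finite(mu)) || any(!is.finite(sigma2)) ||
      any(!is.finite(logS)))
    stop("non-finite inputs")
  if (any(sigma2 <= 0)) stop("sigma2 must be positive")
  .plnDensity(y, mu, sigma2, logS, nNodes = nNodes)
}

#' Background-phase count probability
#'
#' P(Y = y | background) under ZIP(p0, lambda):
#' `p0 * 1[y = 0] + (1 - p0) * dpois(y, lambda)`.
#'
#' @param y non-negative integer count(s).
#' @param p0 zero-inflation mass in [0, 1].
#' @param lam Poisson rate, > 0.
#' @return probabilities in [0, 1].
#' @examples
#' backgroundDensity(0, 0.3, 1)  # 0.3 + 0.7 * exp(-1)
#' @export
backgroundDensity <- function(y, p0, lam) {
  if (any(p0 < 0 | p0 > 1)) stop("p0 must lie in [0, 1]")
  if (any(lam <= 0)) stop("lam must be positive")
  p0 * (y == 0) + (1 - p0) * stats::dpois(y, lam)
}

#' ZIP quantile
#'
#' Smallest `q` with `p0 + (1 - p0) * ppois(q, lam) >= p`.
#'
#' @inheritParams backgroundDensity
#' @param p probability level.
#' @return integer quantile(s).
#' @export
zipQuantile <- function(p, p0, lam) {
  stats::qpois(pmax(0, (p - p0) / (1 - p0)), lam)
}

#' Initial phase indicators
#'
#' A gene-cell observation starts in the active phase when its count exceeds
#' the upper tail of that cell's ZIP background (the `tailProb` quantile,
#' default 0.999); zero counts are always background-compatible.
#'
#' @param x count container accepted by the package.
#' @param bg a [BackgroundParams-class].
#' @param tailProb background tail probability for the cutoff.
#' @return 0/1 integer matrix, genes x cells.
#' @export
initPhase <- function(x, bg, tailProb = 0.999) {
  m <- .asCounts(x)
  stopifnot(identical(colnames(m), bg@cellIds))
  q <- zipQuantile(tailProb, bg@p0, bg@lambda)
  z <- sweep(m, 2L, q, ">")
  storage.mode(z) <- "integer"
  z
}

#' EM fit of the two-phase mixture
#'
#' Treats both the phase `Z` and the active-phase log concentration `u` as
#' latent. The E-step computes the posterior activation probabilities
#' `Z = pi f_act / (pi f_act + (1 - pi) f_bg)` together with the posterior
#' moments of `u` given each count (by the same mode-centred quadrature as
#' [activeDensity()]); the M-step sets `pi_g` to the mean posterior and
#' `mu_g`, `sigma2_g` to the `Z`-weighted posterior mean and variance of `u`
#' over cells with `Y >= 1` (variance floored at `sigma2Floor`). For large
#' counts the posterior of `u` concentrates at `log Y - logS`, so the update
#' reduces to the weighted moments of the observed log counts; being an exact
#' EM step, it keeps the log-likelihood trace non-decreasing. Genes whose
#' active-phase weight mass over non-zero counts falls below `minActiveMass`
#' effective cells are unestimable: their parameters are `NA` and their
#' posterior is the ZIP-tail indicator of [initPhase()], determined by the
#' background alone.
#'
#' Iteration stops when the largest absolute change in `mu` and `pi` drops
#' below `tol`, or after `maxIter` iterations. The total log-likelihood over
#' estimable genes is recorded per iteration.
#'
#' @param x count container accepted by the package.
#' @param bg a [BackgroundParams-class].
#' @param logS optional genes x cells matrix of known log bias factors
#'   (defaults to zero: the first pass, before factors exist).
#' @param maxIter,tol stopping rule (defaults 100, 1e-4).
#' @param nNodes quadrature nodes for the active-phase pmf.
#' @param sigma2Floor lower bound for `sigma2` (log scale, default 0.01).
#' @param minActiveMass minimum effective active cells for estimability.
#' @param initTailProb background tail probability for the initial phase call.
#' @param verbose log one line per iteration (index, log-likelihood, largest
#'   parameter change).
#' @param seed unused by the (deterministic) EM; accepted for API uniformity.
#' @return a [TwoPhaseFit-class].
#' @export
emFit <- function(x, bg, logS = NULL, maxIter = 100L, tol = 1e-4,
                  nNodes = 25L, sigma2Floor = 0.01, minActiveMass = 3,
                  initTailProb = 0.999, verbose = FALSE, seed = NULL) {
  m <- .asCounts(x)
  stopifnot(identical(colnames(m), bg@cellIds))
  G <- nrow(m); n <- ncol(m)
  ls <- if (is.null(logS)) matrix(0, G, n) else {
    stopifnot(all(dim(logS) == c(G, n)))
    ifelse(is.na(logS), 0, logS)
  }

  # per-entry constants
  X <- ifelse(m >= 1L, log(pmax(m, 1L)) - ls, 0)   # active-phase log signal
  fBg <- backgroundDensity(
    m,
    p0 = matrix(bg@p0, G, n, byrow = TRUE),
    lam = matrix(bg@lambda, G, n, byrow = TRUE)
  )
  fBg <- pmax(fBg, 1e-300)

  Zinit <- initPhase(m, bg, initTailProb)
  Z <- Zinit

  # initial parameters from the hard phase calls and the observed log counts
  # (the posterior of u concentrates there for clearly active counts)
  initPar <- function(Z) {
    w <- Z * (m >= 1L)
    mass <- rowSums(w)
    mu <- rowSums(w * X) / mass
    sig2 <- pmax(rowSums(w * (X - mu)^2) / mass, sigma2Floor)
    list(pi = rowMeans(Z), mu = mu, sigma2 = sig2, mass = mass)
  }

  par <- initPar(Z)
  est <- par$mass >= minActiveMass & is.finite(par$mu)
  if (!any(est)) stop("no estimable gene: every gene is background-only")

  # The likelihood factorizes over genes (background parameters are fixed),
  # so each gene's EM runs independently: genes whose mu and pi change by
  # less than tol are frozen and their log-likelihood contribution cached,
  # leaving later iterations to the slow-converging genes only.
  llGene <- rep(NA_real_, G)
  upd <- est
  ll <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    gidx <- which(upd)
    Ge <- length(gidx)
    mg <- m[gidx, , drop = FALSE]
    pln <- .plnDensity(as.vector(mg),
                       rep(par$mu[gidx], n), rep(par$sigma2[gidx], n),
                       as.vector(ls[gidx, , drop = FALSE]),
                       nNodes = nNodes, moments = TRUE)
    fAct <- matrix(pln$p, Ge, n)
    piE <- pmin(pmax(par$pi[gidx], 1e-12), 1 - 1e-12)
    mix <- pmax(piE * fAct + (1 - piE) * fBg[gidx, , drop = FALSE], 1e-300)
    llGene[gidx] <- rowSums(log(mix))
    ll[it] <- sum(llGene[est])
    Znew <- (piE * fAct) / mix
    Z[gidx, ] <- Znew
    # exact M-step on the latent log concentration
    w <- Znew * (mg >= 1L)
    mass <- rowSums(w)
    m1 <- matrix(pln$m1, Ge, n)
    m2 <- matrix(pln$m2, Ge, n)
    muNew <- rowSums(w * m1) / mass
    s2New <- pmax(rowSums(w * (m2 - 2 * muNew * m1 + muNew^2)) / mass,
                  sigma2Floor)
    piNew <- rowMeans(Znew)
    dg <- pmax(abs(muNew - par$mu[gidx]), abs(piNew - par$pi[gidx]))
    dg[!is.finite(dg)] <- Inf
    ok <- mass >= minActiveMass & is.finite(muNew)
    par$mu[gidx] <- muNew
    par$sigma2[gidx] <- s2New
    par$pi[gidx] <- piNew
    par$mass[gidx] <- mass
    est[gidx] <- ok
    upd[gidx] <- ok & dg >= tol
    .msg(verbose, "EM iter %d: logLik %.6f, max param change %.3g (%d genes open)",
         it, ll[it], max(dg[is.finite(dg)], 0), sum(upd))
    if (!any(est)) stop("no estimable gene left during EM")
    if (!any(upd)) { converged <- TRUE; break }
  }

  mu <- par$mu; sig2 <- par$sigma2; piA <- par$pi
  mu[!est] <- NA_real_; sig2[!est] <- NA_real_
  if (any(!est)) {
    Z[!est, ] <- Zinit[!est, ]
    piA[!est] <- rowMeans(Zinit[!est, , drop = FALSE])
  }
  methods::new("TwoPhaseFit",
    geneIds = rownames(m), cellIds = colnames(m),
    mu = unname(mu), sigma2 = unname(sig2), piActive = unname(piA),
    estimable = unname(est), Zpost = Z, loglikTrace = ll,
    nIter = it, converged = converged, background = bg)
}

#' Hard phase calls
#'
#' Boolean genes x cells matrix of `Zpost > threshold` (strict inequality;
#' default 0.99).
#'
#' @param fit a [TwoPhaseFit-class].
#' @param threshold posterior cutoff in (0, 1).
#' @return logical matrix.
#' @export
phaseCall <- function(fit, threshold = 0.99) {
  stopifnot(threshold > 0, threshold < 1)
  fit@Zpost > threshold
}

#' Background estimation plus EM in one call
#'
#' Convenience wrapper: [estimateBackground()] followed by [emFit()].
#'
#' @inheritParams emFit
#' @inheritParams estimateBackground
#' @param ... passed on to [emFit()].
#' @return a [TwoPhaseFit-class].
#' @export
fitTwoPhase <- function(x, yMax = 10L, robustIters = 20L, verbose = FALSE,
                        ...) {
  bg <- estimateBackground(x, yMax = yMax, robustIters = robustIters,
                           verbose = verbose)
  emFit(x, bg, verbose = verbose, ...)
}
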
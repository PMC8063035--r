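# Shared fixtures and fitted objects, generated once per test run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

fx <- function(name) {
  cached(paste0("fx_", name), fixtureSuite(name)[[name]])
}

fxFit <- function(name) {
  cached(paste0("fit_", name), fitTwoPhase(fx(name)))
}

fxNorm <- function(name, mode = "at_mu") {
  cached(paste0("nf_", name, "_", mode),
         estimateNormFactors(fx(name), fxFit(name), mode = mode))
}

# small labelled count matrix helper
countMat <- function(data, nr, genes = NULL, cells = NULL) {
  m <- matrix(as.integer(data), nrow = nr)
  rownames(m) <- genes %||% sprintf("g%d", seq_len(nrow(m)))
  colnames(m) <- cells %||% sprintf("c%d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force trapezoid oracle for the active-phase pmf
trapActiveDensity <- function(y, mu, s2, ls = 0, n = 10001) {
  u <- seq(mu - 8 * sqrt(s2) - 3, mu + 8 * sqrt(s2) + 3, length.out = n)
  f <- stats::dpois(y, exp(u + ls)) * stats::dnorm(u, mu, sqrt(s2))
  sum((f[-1] + f[-n]) / 2) * diff(u[1:2])
}

# draw a pure ZIP count vector
rzip <- function(G, p0, lam) {
  ifelse(stats::rbinom(G, 1, p0) == 1, 0L, stats::rpois(G, lam))
}
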
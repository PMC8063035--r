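# Internal helpers shared across modules.

# Extract a validated genes x cells count matrix from the containers the
# package accepts: a base matrix, a (Single Cell) SummarizedExperiment with a
# "counts" assay, or a SimTruth.
.asCounts <- function(x) {
  if (is(x, "SimTruth")) {
    m <- x@counts
  } else if (is(x, "SummarizedExperiment")) {
    nm <- SummarizedExperiment::assayNames(x)
    use <- if ("counts" %in% nm) "counts" else 1L
    m <- as.matrix(SummarizedExperiment::assay(x, use))
  } else if (is(x, "Matrix")) {
    m <- as.matrix(x)
  } else if (is.matrix(x)) {
    m <- x
  } else {
    stop("cannot interpret 'x' as a count matrix (matrix, ",
         "SummarizedExperiment or SimTruth expected)")
  }
  .checkCountMatrix(m)
  m
}

.checkCountMatrix <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("count matrix must carry gene ids (rownames) and cell ids (colnames)")
  if (anyDuplicated(rownames(m)))
    stop("validation error: duplicate gene ids")
  if (anyDuplicated(colnames(m)))
    stop("validation error: duplicate cell ids")
  if (anyNA(m) || any(m < 0))
    stop("counts must be non-negative and complete")
  if (any(m != round(m)))
    stop("counts must be integers")
  invisible(m)
}

# Weighted median (lower interpolation), used for robust scale estimates.
.wmedian <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1L]]
}

# One robust line fit on (x, y) with base weights wBase: initialized from the
# two lowest-x points (in this package, the least contaminated count bins),
# then Tukey bisquare IRLS (tuning constant 4.685) with the robust scale taken
# as a wBase-weighted median of sqrt(wBase)-standardized absolute residuals.
# robustIters = 0 gives the plain weighted least-squares fit.
.robustLine <- function(x, y, wBase, robustIters = 20L, tuning = 4.685) {
  X <- cbind(1, x)
  if (robustIters <= 0)
    return(stats::lm.wfit(X, y, wBase)$coefficients)
  sl <- (y[2L] - y[1L]) / (x[2L] - x[1L])
  cf <- c(y[1L] - x[1L] * sl, sl)
  for (k in seq_len(robustIters)) {
    r <- y - (cf[1L] + cf[2L] * x)
    z <- r * sqrt(wBase)
    s <- .wmedian(abs(z), wBase) / 0.6745
    s <- max(s, 1e-8)
    u <- pmin(abs(z / (tuning * s)), 1)
    wt <- wBase * (1 - u^2)^2
    if (sum(wt > 0) < 2L) break
    cf <- stats::lm.wfit(X, y, wt)$coefficients
  }
  cf
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.msg <- function(verbose, ...) if (isTRUE(verbose)) message(sprintf(...))
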
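# Accessors and show methods for the core classes.

#' @rdname TwoPhaseFit-class
#' @param object,x a fitted object
#' @export
setGeneric("posteriorActive", function(object) standardGeneric("posteriorActive"))

#' @rdname TwoPhaseFit-class
#' @export
setMethod("posteriorActive", "TwoPhaseFit", function(object) object@Zpost)

#' @rdname TwoPhaseFit-class
#' @export
setGeneric("geneParams", function(object) standardGeneric("geneParams"))

#' @describeIn TwoPhaseFit-class per-gene parameter table (one row per gene:
#'   mu, sigma2, pi, effective number of active cells, estimability).
#' @export
setMethod("geneParams", "TwoPhaseFit", function(object) {
  data.frame(
    gene_id = object@geneIds,
    mu_hat = object@mu,
    sigma2_hat = object@sigma2,
    pi_hat = object@piActive,
    n_active = as.integer(round(rowSums(object@Zpost))),
    estimable = object@estimable,
    stringsAsFactors = FALSE, row.names = NULL
  )
})

#' @rdname TwoPhaseFit-class
#' @export
setGeneric("logLikTrace", function(object) standardGeneric("logLikTrace"))

#' @rdname TwoPhaseFit-class
#' @export
setMethod("logLikTrace", "TwoPhaseFit", function(object) object@loglikTrace)

#' @rdname BackgroundParams-class
#' @param object a \code{BackgroundParams}
#' @export
setGeneric("cellParams", function(object) standardGeneric("cellParams"))

#' @describeIn BackgroundParams-class per-cell parameter table.
#' @export
setMethod("cellParams", "BackgroundParams", function(object) {
  data.frame(
    cell_id = object@cellIds,
    p0_hat = object@p0,
    lam_hat = object@lambda,
    n_bg_hat = object@nBgHat,
    L = object@librarySize,
    flagged = object@flagged,
    stringsAsFactors = FALSE, row.names = NULL
  )
})

#' @rdname NormFactorMatrix-class
#' @param object a \code{NormFactorMatrix}
#' @export
setGeneric("logS", function(object) standardGeneric("logS"))

#' @describeIn NormFactorMatrix-class the genes x cells matrix of log
#'   normalization factors, NA where the gene is not active in the cell.
#' @export
setMethod("logS", "NormFactorMatrix", function(object) object@logS)

#' @rdname NormFactorMatrix-class
#' @export
setGeneric("biasCurves", function(object) standardGeneric("biasCurves"))

#' @rdname NormFactorMatrix-class
#' @export
setMethod("biasCurves", "NormFactorMatrix", function(object) object@curves)

#' @rdname NormFactorMatrix-class
#' @export
setGeneric("referenceCell", function(object) standardGeneric("referenceCell"))

#' @rdname NormFactorMatrix-class
#' @export
setMethod("referenceCell", "NormFactorMatrix", function(object) object@referenceCell)

#' @rdname LibrarySizes-class
#' @export
setMethod("referenceCell", "LibrarySizes", function(object) object@referenceCell)

#' @rdname SimTruth-class
#' @param object a \code{SimTruth}
#' @export
setGeneric("simCounts", function(object) standardGeneric("simCounts"))

#' @describeIn SimTruth-class the realized count matrix.
#' @export
setMethod("simCounts", "SimTruth", function(object) object@counts)

#' @rdname SimTruth-class
#' @export
setGeneric("simTruth", function(object) standardGeneric("simTruth"))

#' @describeIn SimTruth-class all ground-truth components as a list.
#' @export
setMethod("simTruth", "SimTruth", function(object) {
  list(
    mu = object@mu, sigma = object@sigma, piActive = object@piActive,
    p0 = object@p0, lambda = object@lambda, Z = object@Z,
    logS = object@logS, groups = object@groups, deGenes = object@deGenes
  )
})

setMethod("show", "BackgroundParams", function(object) {
  cat(sprintf(
    "BackgroundParams: %d cells (yMax = %d)\n  p0 in [%.3f, %.3f], lambda in [%.3f, %.3f], %d flagged\n",
    length(object@cellIds), object@yMax,
    min(object@p0), max(object@p0),
    min(object@lambda), max(object@lambda), sum(object@flagged)
  ))
})

setMethod("show", "TwoPhaseFit", function(object) {
  cat(sprintf(
    "TwoPhaseFit: %d genes x %d cells\n  %d estimable genes, %d EM iterations (%s)\n  final logLik %.4f\n",
    length(object@geneIds), length(object@cellIds),
    sum(object@estimable), object@nIter,
    if (object@converged) "converged" else "not converged",
    utils::tail(object@loglikTrace, 1)
  ))
})

setMethod("show", "NormFactorMatrix", function(object) {
  cat(sprintf(
    "NormFactorMatrix: %d genes x %d cells\n  reference cell %s%s, %d/%d spline curves\n",
    length(object@geneIds), length(object@cellIds), object@referenceCell,
    if (object@rescaled) " (mean S constrained to 1)" else " (unscaled)",
    sum(object@curveFallback == "spline"), length(object@cellIds)
  ))
})

setMethod("show", "LibrarySizes", function(object) {
  cat(sprintf(
    "LibrarySizes: %d cells, L in [%d, %d], reference %s (L0 = %d)\n",
    length(object@L), min(object@L), max(object@L),
    object@referenceCell, as.integer(object@L0)
  ))
})

setMethod("show", "SimTruth", function(object) {
  cat(sprintf(
    "SimTruth: %d genes x %d cells (bias model '%s', seed %d)\n",
    nrow(object@counts), ncol(object@counts),
    if (is.null(object@config$biasModel)) "none" else object@config$biasModel,
    object@seed
  ))
})
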
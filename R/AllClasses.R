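#' @import methods
NULL

#' Per-cell zero-inflated Poisson background parameters
#'
#' Container for the estimated background (inactive-phase) count distribution
#' of each cell: a zero-inflated Poisson ZIP(p0, lambda) with point mass
#' \code{p0} at zero and Poisson rate \code{lambda}, together with the implied
#' number of background-phase genes and a flag for cells whose estimate was
#' imputed from the cohort median.
#'
#' @slot cellIds character, one id per cell.
#' @slot p0 numeric, zero-inflation mass per cell, in [0, 1].
#' @slot lambda numeric, Poisson rate per cell, > 0.
#' @slot nBgHat numeric, implied number of background-phase genes per cell.
#' @slot flagged logical, TRUE for cells whose estimation failed and whose
#'   parameters were imputed from the median of successful cells.
#' @slot librarySize numeric, total count per cell.
#' @slot yMax integer, upper count bound used in the log-frequency regression.
#'
#' @seealso [estimateBackground()], [estimateZIP()]
#' @export
setClass("BackgroundParams",
  representation(
    cellIds = "character",
    p0 = "numeric",
    lambda = "numeric",
    nBgHat = "numeric",
    flagged = "logical",
    librarySize = "numeric",
    yMax = "integer"
  )
)

setValidity("BackgroundParams", function(object) {
  n <- length(object@cellIds)
  if (anyDuplicated(object@cellIds))
    return("cell ids must be unique")
  for (s in c("p0", "lambda", "nBgHat", "flagged", "librarySize"))
    if (length(slot(object, s)) != n)
      return(sprintf("slot '%s' must have one entry per cell", s))
  if (any(object@p0 < 0 | object@p0 > 1, na.rm = TRUE))
    return("p0 must lie in [0, 1]")
  if (any(object@lambda <= 0, na.rm = TRUE))
    return("lambda must be positive")
  TRUE
})

#' Two-phase mixture fit
#'
#' Result of the per-gene EM fit of the two-phase model: for every gene an
#' active-phase lognormal location \code{mu} and scale \code{sigma2} (natural
#' log), a prior activation probability \code{piActive}, and for every
#' gene-cell pair the posterior probability \code{Zpost} that the observation
#' came from the active phase. Genes whose active-phase weight mass fell below
#' the estimability floor carry \code{NA} parameters and are marked in
#' \code{estimable}; their posterior is the background-tail indicator.
#'
#' @slot geneIds,cellIds character identifiers.
#' @slot mu,sigma2,piActive per-gene numeric parameters (NA if unestimable).
#' @slot estimable logical per gene.
#' @slot Zpost numeric matrix, genes x cells, in [0, 1].
#' @slot loglikTrace numeric, total log-likelihood per EM iteration.
#' @slot nIter integer, iterations used.
#' @slot converged logical.
#' @slot background the [BackgroundParams-class] used in the fit.
#'
#' @seealso [emFit()], [fitTwoPhase()], [phaseCall()]
#' @export
setClass("TwoPhaseFit",
  representation(
    geneIds = "character",
    cellIds = "character",
    mu = "numeric",
    sigma2 = "numeric",
    piActive = "numeric",
    estimable = "logical",
    Zpost = "matrix",
    loglikTrace = "numeric",
    nIter = "integer",
    converged = "logical",
    background = "BackgroundParams"
  )
)

setValidity("TwoPhaseFit", function(object) {
  G <- length(object@geneIds); n <- length(object@cellIds)
  if (!all(dim(object@Zpost) == c(G, n)))
    return("Zpost must be genes x cells")
  if (any(object@Zpost < 0 | object@Zpost > 1, na.rm = TRUE))
    return("Zpost entries must lie in [0, 1]")
  p <- object@piActive
  if (any(p < 0 | p > 1, na.rm = TRUE))
    return("piActive must lie in [0, 1]")
  if (any(object@sigma2 <= 0, na.rm = TRUE))
    return("sigma2 must be positive")
  TRUE
})

#' Per-gene-per-cell log normalization factors
#'
#' Holds the matrix of log technical-bias factors log S for every gene-cell
#' pair (NA where the gene is not called active in that cell), the per-cell
#' smooth bias curves they were read off of, and the reference cell whose
#' average factor is constrained to 1.
#'
#' @slot logS numeric matrix, genes x cells, NA on masked (background) entries.
#' @slot curves named list of per-cell curve objects (see [evalCurve()]).
#' @slot referenceCell id of the median-depth reference cell.
#' @slot nActive integer, number of active genes per cell.
#' @slot curveFallback character per cell: "spline", "constant" or "cohort".
#' @slot rescaled logical, TRUE once the reference-cell constraint holds.
#' @slot geneIds,cellIds character identifiers.
#'
#' @seealso [estimateNormFactors()], [rescaleToReference()],
#'   [applyNormFactors()]
#' @export
setClass("NormFactorMatrix",
  representation(
    geneIds = "character",
    cellIds = "character",
    logS = "matrix",
    curves = "list",
    referenceCell = "character",
    nActive = "integer",
    curveFallback = "character",
    rescaled = "logical"
  )
)

setValidity("NormFactorMatrix", function(object) {
  G <- length(object@geneIds); n <- length(object@cellIds)
  if (!all(dim(object@logS) == c(G, n)))
    return("logS must be genes x cells")
  if (any(is.infinite(object@logS), na.rm = TRUE))
    return("logS must be finite wherever unmasked")
  if (length(object@referenceCell) != 1 ||
      !(object@referenceCell %in% object@cellIds))
    return("referenceCell must name one of the cells")
  TRUE
})

#' Library sizes and the median-depth reference cell
#'
#' @slot L named numeric, total count per cell.
#' @slot referenceCell id of the cell with the median library size (for an
#'   even number of cells, the lower of the two middle values, so that the
#'   reference is always an actual cell; ties resolved to the first cell in
#'   column order).
#' @slot L0 library size of the reference cell.
#'
#' @seealso [librarySizes()]
#' @export
setClass("LibrarySizes",
  representation(L = "numeric", referenceCell = "character", L0 = "numeric")
)

setValidity("LibrarySizes", function(object) {
  if (is.null(names(object@L))) return("L must be named by cell id")
  if (!(object@referenceCell %in% names(object@L)))
    return("referenceCell must be one of the cells")
  TRUE
})

#' Simulated two-phase counts with ground truth
#'
#' A simulated genes x cells count matrix together with every latent quantity
#' that generated it: gene-level (mu, sigma, pi), cell-level ZIP background
#' (p0, lambda), the phase matrix Z, and the true log bias factors log S.
#'
#' @slot counts integer matrix, genes x cells, with dimnames.
#' @slot mu,sigma,piActive numeric per gene.
#' @slot p0,lambda numeric per cell.
#' @slot Z integer matrix of true phases (1 = active).
#' @slot logS numeric matrix of true log bias factors.
#' @slot groups character per cell (empty if the design has no groups).
#' @slot deGenes ids of genes simulated with a true group effect.
#' @slot config the simulation configuration, as a list.
#' @slot seed integer seed the draw started from.
#'
#' @seealso [simulateTwoPhase()], [fixtureSuite()]
#' @export
setClass("SimTruth",
  representation(
    counts = "matrix",
    mu = "numeric",
    sigma = "numeric",
    piActive = "numeric",
    p0 = "numeric",
    lambda = "numeric",
    Z = "matrix",
    logS = "matrix",
    groups = "character",
    deGenes = "character",
    config = "list",
    seed = "integer"
  )
)

setValidity("SimTruth", function(object) {
  if (any(object@counts < 0) || any(object@counts != round(object@counts)))
    return("counts must be non-negative integers")
  if (is.null(rownames(object@counts)) || is.null(colnames(object@counts)))
    return("counts must carry gene and cell ids as dimnames")
  TRUE
})
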
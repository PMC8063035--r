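#' Read a genes x cells count matrix
#'
#' Reads non-negative integer read counts in either of two plain-text layouts:
#' a dense TSV (header row of cell ids, first column of gene ids) or a Matrix
#' Market coordinate file with 1-based indices accompanied by `genes.txt` and
#' `cells.txt` sidecar files (one id per line). Rows are genes, columns are
#' cells, throughout the package.
#'
#' @param path path to the matrix file.
#' @param format `"tsv"`, `"mtx"`, or `"auto"` (decide from the extension).
#' @param genesFile,cellsFile sidecar id files for the Matrix Market layout;
#'   default to `genes.txt` / `cells.txt` next to `path`.
#' @return a [SingleCellExperiment::SingleCellExperiment] with a validated
#'   integer `counts` assay.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\tc1\tc2", "g1\t0\t5", "g2\t2\t0"), tf)
#' sce <- readCounts(tf)
#' SummarizedExperiment::assay(sce, "counts")
#' @export
readCounts <- function(path, format = c("auto", "tsv", "mtx"),
                       genesFile = NULL, cellsFile = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "tsv"
  }
  m <- if (format == "tsv") .readDenseTSV(path)
       else .readMTX(path, genesFile, cellsFile)
  .checkCountMatrix(m)
  SingleCellExperiment::SingleCellExperiment(assays = list(counts = m))
}

.readDenseTSV <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  cells <- header[-1L]
  body <- utils::read.delim(path, header = TRUE, sep = "\t",
                            colClasses = "character", check.names = FALSE)
  genes <- body[[1L]]
  raw <- as.matrix(body[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- which(!is.finite(num) | num != floor(num) | num < 0)
  if (length(bad)) {
    ij <- arrayInd(bad[1L], dim(num))
    stop(sprintf(
      "parse error in %s, line %d: entry '%s' (gene %s, cell %s) is not a non-negative integer",
      path, ij[1L] + 1L, raw[bad[1L]], genes[ij[1L]], cells[ij[2L]]))
  }
  storage.mode(num) <- "integer"
  dimnames(num) <- list(genes, cells)
  num
}

.readMTX <- function(path, genesFile, cellsFile) {
  d <- dirname(path)
  genesFile <- genesFile %||% file.path(d, "genes.txt")
  cellsFile <- cellsFile %||% file.path(d, "cells.txt")
  for (f in c(genesFile, cellsFile))
    if (!file.exists(f)) stop("sidecar id file not found: ", f)
  sp <- Matrix::readMM(path)
  m <- as.matrix(sp)
  if (any(m != round(m)) || any(m < 0))
    stop("parse error in ", path, ": non-integer or negative entries")
  storage.mode(m) <- "integer"
  genes <- readLines(genesFile)
  cells <- readLines(cellsFile)
  if (length(genes) != nrow(m) || length(cells) != ncol(m))
    stop("sidecar id files do not match the matrix dimensions")
  dimnames(m) <- list(genes, cells)
  m
}

#' Write a count matrix
#'
#' Inverse of [readCounts()]: dense TSV or Matrix Market plus id sidecars.
#'
#' @param x count container accepted by the package.
#' @param path output file.
#' @inheritParams readCounts
#' @return `path`, invisibly.
#' @export
writeCounts <- function(x, path, format = c("tsv", "mtx"),
                        genesFile = NULL, cellsFile = NULL) {
  format <- match.arg(format)
  m <- .asCounts(x)
  if (format == "tsv") {
    .writeDenseTSV(m, path, corner = "gene_id")
  } else {
    d <- dirname(path)
    Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"),
                    path)
    writeLines(rownames(m), genesFile %||% file.path(d, "genes.txt"))
    writeLines(colnames(m), cellsFile %||% file.path(d, "cells.txt"))
  }
  invisible(path)
}

.writeDenseTSV <- function(m, path, corner = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(corner, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.readDenseNumericTSV <- function(path) {
  body <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE)
  m <- as.matrix(body[, -1L, drop = FALSE])
  rownames(m) <- as.character(body[[1L]])
  m
}

#' Library sizes and the reference cell
#'
#' Computes each cell's library size (column sum of counts) and identifies the
#' reference cell: the cell whose library size is the median. For an even
#' number of cells the lower of the two middle values is taken so that the
#' reference is always an actual cell; ties go to the first such cell in
#' column order.
#'
#' @param x count container accepted by the package.
#' @return a [LibrarySizes-class].
#' @examples
#' m <- matrix(c(1, 3, 2, 4), 2, dimnames = list(c("g1", "g2"), c("c1", "c2")))
#' librarySizes(m)
#' @export
librarySizes <- function(x) {
  m <- .asCounts(x)
  L <- colSums(m)
  if (all(L == 0)) stop("no non-empty cells")
  lower <- sort(L)[floor((length(L) + 1) / 2)]
  ref <- colnames(m)[which(L == lower)[1L]]
  methods::new("LibrarySizes", L = L, referenceCell = ref, L0 = unname(L[ref]))
}

#' Write a complete fit to a directory
#'
#' Serializes a two-phase fit and its normalization factors as plain-text
#' tables: `gene_params.tsv`, `cell_params.tsv`, dense `Z_post.tsv` and
#' `log_s.tsv` matrices (masked background entries written as the literal
#' `NA`), `curves.tsv` with the spline knots and coefficients of every cell's
#' bias curve, and `meta.json` with scalar fit metadata. Everything round-trips
#' through [readResults()]. Optionally also writes the adjusted count matrix.
#'
#' @param fit a [TwoPhaseFit-class].
#' @param nf a [NormFactorMatrix-class] sharing the fit's gene/cell ids.
#' @param outdir output directory, created if needed.
#' @param counts optional count container; when given, the adjusted matrix is
#'   written as `normalized.tsv`.
#' @return `outdir`, invisibly.
#' @export
writeResults <- function(fit, nf, outdir, counts = NULL) {
  stopifnot(is(fit, "TwoPhaseFit"), is(nf, "NormFactorMatrix"))
  if (length(fit@geneIds) == 0L) stop("empty gene set")
  if (!identical(fit@geneIds, nf@geneIds) ||
      !identical(fit@cellIds, nf@cellIds))
    stop("fit and normalization factors must share gene and cell ids")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot write to ", outdir)

  utils::write.table(geneParams(fit), file.path(outdir, "gene_params.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cp <- cellParams(fit@background)
  cp$n_active_genes <- nf@nActive[match(cp$cell_id, nf@cellIds)]
  utils::write.table(cp, file.path(outdir, "cell_params.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .writeDenseTSV(fit@Zpost, file.path(outdir, "Z_post.tsv"))
  .writeDenseTSV(nf@logS, file.path(outdir, "log_s.tsv"))
  .writeCurvesTSV(nf@curves, file.path(outdir, "curves.tsv"))
  meta <- list(
    gene_ids = fit@geneIds, cell_ids = fit@cellIds,
    loglik_trace = fit@loglikTrace, n_iter = fit@nIter,
    converged = fit@converged, y_max = fit@background@yMax,
    reference_cell = nf@referenceCell, rescaled = nf@rescaled,
    curve_fallback = nf@curveFallback
  )
  jsonlite::write_json(meta, file.path(outdir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(counts)) {
    adj <- applyNormFactors(counts, nf, mode = "adjusted")
    .writeDenseTSV(adj, file.path(outdir, "normalized.tsv"))
  }
  invisible(outdir)
}

.writeCurvesTSV <- function(curves, path) {
  rows <- lapply(names(curves), function(cell) {
    cv <- curves[[cell]]
    out <- list(
      data.frame(cell_id = cell, param = "type", index = 1L,
                 value = match(cv$type, c("spline", "constant", "cohort")),
                 stringsAsFactors = FALSE),
      data.frame(cell_id = cell, param = "range", index = 1:2, value = cv$xr)
    )
    if (cv$type == "spline") {
      if (length(cv$knots))
        out <- c(out, list(data.frame(cell_id = cell, param = "knot",
                                      index = seq_along(cv$knots),
                                      value = cv$knots)))
      out <- c(out, list(
        data.frame(cell_id = cell, param = "bknot", index = 1:2,
                   value = cv$boundary),
        data.frame(cell_id = cell, param = "coef",
                   index = seq_along(cv$coef), value = cv$coef)
      ))
    } else if (cv$type == "constant") {
      out <- c(out, list(data.frame(cell_id = cell, param = "const",
                                    index = 1L, value = cv$value)))
    } else {
      out <- c(out, list(
        data.frame(cell_id = cell, param = "gridx",
                   index = seq_along(cv$gridX), value = cv$gridX),
        data.frame(cell_id = cell, param = "gridy",
                   index = seq_along(cv$gridY), value = cv$gridY)
      ))
    }
    do.call(rbind, out)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

.readCurvesTSV <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  out <- lapply(split(tab, factor(tab$cell_id, unique(tab$cell_id))),
                function(d) {
    get <- function(p) d$value[d$param == p][order(d$index[d$param == p])]
    type <- c("spline", "constant", "cohort")[get("type")]
    cv <- list(type = type, xr = get("range"))
    if (type == "spline") {
      cv$knots <- get("knot")
      cv$boundary <- get("bknot")
      cv$coef <- get("coef")
    } else if (type == "constant") {
      cv$value <- get("const")
    } else {
      cv$gridX <- get("gridx")
      cv$gridY <- get("gridy")
    }
    cv
  })
  out[unique(tab$cell_id)]
}

#' Read back a directory written by [writeResults()]
#'
#' @param outdir directory produced by [writeResults()].
#' @return a list with elements `fit` ([TwoPhaseFit-class]) and `nf`
#'   ([NormFactorMatrix-class]).
#' @export
readResults <- function(outdir) {
  meta <- jsonlite::read_json(file.path(outdir, "meta.json"),
                              simplifyVector = TRUE)
  gp <- utils::read.delim(file.path(outdir, "gene_params.tsv"),
                          stringsAsFactors = FALSE)
  cp <- utils::read.delim(file.path(outdir, "cell_params.tsv"),
                          stringsAsFactors = FALSE)
  Z <- .readDenseNumericTSV(file.path(outdir, "Z_post.tsv"))
  lS <- .readDenseNumericTSV(file.path(outdir, "log_s.tsv"))
  colnames(Z) <- colnames(lS) <- meta$cell_ids
  bg <- methods::new("BackgroundParams",
    cellIds = cp$cell_id, p0 = cp$p0_hat, lambda = cp$lam_hat,
    nBgHat = cp$n_bg_hat, flagged = cp$flagged, librarySize = cp$L,
    yMax = as.integer(meta$y_max))
  fit <- methods::new("TwoPhaseFit",
    geneIds = gp$gene_id, cellIds = cp$cell_id,
    mu = gp$mu_hat, sigma2 = gp$sigma2_hat, piActive = gp$pi_hat,
    estimable = gp$estimable, Zpost = Z,
    loglikTrace = as.numeric(meta$loglik_trace),
    nIter = as.integer(meta$n_iter), converged = as.logical(meta$converged),
    background = bg)
  nf <- methods::new("NormFactorMatrix",
    geneIds = gp$gene_id, cellIds = cp$cell_id, logS = lS,
    curves = .readCurvesTSV(file.path(outdir, "curves.tsv")),
    referenceCell = meta$reference_cell,
    nActive = as.integer(cp$n_active_genes),
    curveFallback = as.character(meta$curve_fallback),
    rescaled = as.logical(meta$rescaled))
  list(fit = fit, nf = nf)
}
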
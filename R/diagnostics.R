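# Diagnostics: count-depth statistics, phase-split MA tables, conditional SD
# ratios, stratified group log fold changes, ARI, and a trivial size-factor
# baseline for contrast. All outputs are tidy tables; all functions are pure.

#' Count-depth relationship per gene
#'
#' For each gene passing a mean-log-expression filter, the slope of
#' `log(Y + pseudo)` regressed on `log(L)` across cells, and the Pearson
#' correlation between the gene's values and the library size. Run on raw
#' counts this measures the technical count-depth relationship; run on a
#' normalized matrix it measures what normalization left behind.
#'
#' @param x genes x cells matrix (raw or normalized values) or count
#'   container.
#' @param ls a [LibrarySizes-class]; computed from `x` when missing (pass one
#'   computed from the raw counts when `x` is normalized).
#' @param minMeanLog include genes with mean log counts above this (default 4;
#'   set to `-Inf` to keep all genes).
#' @param base log base for the filter and slope (default 2).
#' @param pseudo pseudo-count (default 1).
#' @return data.frame: `gene_id`, `mean_log`, `slope`, `correlation`
#'   (NA for constant genes).
#' @export
countDepth <- function(x, ls = NULL, minMeanLog = 4, base = 2, pseudo = 1) {
  m <- if (is.matrix(x) && !is.integer(x)) x else .asCounts(x)
  if (ncol(m) < 3L) stop("at least 3 cells required")
  ls <- ls %||% librarySizes(x)
  L <- ls@L[colnames(m)]
  lm_ <- log(m + pseudo) / log(base)
  meanLog <- rowMeans(lm_)
  keep <- which(meanLog > minMeanLog)
  lL <- log(L) / log(base)
  lLc <- lL - mean(lL)
  denom <- sum(lLc^2)
  slope <- as.vector(lm_[keep, , drop = FALSE] %*% lLc) / denom
  corr <- suppressWarnings(
    as.vector(stats::cor(t(m[keep, , drop = FALSE]), L))
  )
  data.frame(gene_id = rownames(m)[keep], mean_log = meanLog[keep],
             slope = slope, correlation = corr,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Phase-split MA table for one cell
#'
#' For every gene with a non-zero count in the chosen cell and an estimable
#' mean, the mean log expression `mu_hat` (x), the log ratio
#' `log Y - mu_hat` (y), and the phase call - the data behind an MA plot in
#' which only active-phase genes inform the bias curve.
#'
#' @param x count container accepted by the package.
#' @param fit a [TwoPhaseFit-class].
#' @param cell cell id.
#' @param threshold posterior activation cutoff.
#' @param base log base of the output (default natural).
#' @return data.frame: `gene_id`, `mean_log`, `log_ratio`, `phase`.
#' @export
maData <- function(x, fit, cell, threshold = 0.99, base = exp(1)) {
  m <- .asCounts(x)
  i <- match(cell, fit@cellIds)
  if (is.na(i)) stop("unknown cell: ", cell)
  rows <- which(m[, i] >= 1L & fit@estimable)
  data.frame(
    gene_id = fit@geneIds[rows],
    mean_log = fit@mu[rows] / log(base),
    log_ratio = (log(m[rows, i]) - fit@mu[rows]) / log(base),
    phase = ifelse(fit@Zpost[rows, i] > threshold, "active", "background"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

.strataCut <- function(v, nBins) {
  edges <- unique(stats::quantile(v, probs = seq(0, 1, length.out = nBins + 1),
                                  na.rm = TRUE))
  cut(v, breaks = edges, include.lowest = TRUE)
}

#' Conditional standard-deviation ratio, stratified by expression
#'
#' For each gene detected (active) in at least `minCells` cells, the standard
#' deviation of its log values over those cells in the raw and in the
#' normalized data, and their ratio (normalized / raw). Conditioning on
#' detection keeps dropout from masquerading as variability. Genes are
#' stratified into `nBins` mean-expression bins (quantile edges).
#'
#' @param raw,normalized aligned genes x cells matrices.
#' @param fit a [TwoPhaseFit-class] supplying the detection calls.
#' @param nBins number of mean-expression strata (default 4).
#' @param threshold posterior activation cutoff.
#' @param minCells minimum active cells per gene (default 3).
#' @return data.frame: `gene_id`, `mean_log`, `sd_raw`, `sd_norm`, `ratio`,
#'   `stratum`; bin edges in `attr(, "edges")`.
#' @export
conditionalSDRatio <- function(raw, normalized, fit, nBins = 4L,
                               threshold = 0.99, minCells = 3L) {
  stopifnot(all(dim(raw) == dim(normalized)))
  act <- phaseCall(fit, threshold) & raw >= 1
  nAct <- rowSums(act)
  keep <- which(nAct >= minCells)
  stat <- t(vapply(keep, function(g) {
    j <- act[g, ]
    c(mean(log(raw[g, j])),
      stats::sd(log(raw[g, j])),
      stats::sd(log(normalized[g, j])))
  }, numeric(3)))
  out <- data.frame(
    gene_id = rownames(raw)[keep],
    mean_log = stat[, 1L],
    sd_raw = stat[, 2L], sd_norm = stat[, 3L],
    ratio = stat[, 3L] / stat[, 2L],
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$stratum <- .strataCut(out$mean_log, nBins)
  attr(out, "edges") <- levels(out$stratum)
  out
}

#' Two-group log fold changes, stratified by expression
#'
#' Per gene, the difference of group means of `log(value + pseudo)` computed
#' over all cells, and separately over active-only cells, for a two-group
#' design. Under a null design with unbalanced sequencing depth, raw LFCs are
#' shifted away from zero; successful normalization re-centres every
#' expression stratum without shrinking true differences.
#'
#' @param x genes x cells matrix (raw or normalized values).
#' @param groups factor/character of length `ncol(x)` with exactly 2 levels,
#'   each with at least 3 cells. The LFC is level 1 minus level 2.
#' @param fit a [TwoPhaseFit-class] for the active calls.
#' @param nBins number of mean-expression strata.
#' @param threshold posterior activation cutoff.
#' @param base log base (default natural).
#' @param pseudo pseudo-count for the all-cells variant.
#' @return data.frame: `gene_id`, `mean_log`, `lfc_all`, `lfc_active`,
#'   `stratum`.
#' @export
groupLFC <- function(x, groups, fit, nBins = 4L, threshold = 0.99,
                     base = exp(1), pseudo = 1) {
  m <- if (is.matrix(x) && !is.integer(x)) x else .asCounts(x)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L)
    stop("exactly 2 groups required; compare more groups pairwise")
  if (any(table(groups) < 3L)) stop("each group needs at least 3 cells")
  gA <- groups == levels(groups)[1L]
  lmat <- log(m + pseudo) / log(base)
  lfcAll <- rowMeans(lmat[, gA, drop = FALSE]) -
    rowMeans(lmat[, !gA, drop = FALSE])
  act <- phaseCall(fit, threshold) & m >= 1
  lv <- ifelse(m >= 1, log(pmax(m, 1)) / log(base), NA)
  lfcActive <- vapply(seq_len(nrow(m)), function(g) {
    a <- act[g, ] & gA; b <- act[g, ] & !gA
    if (sum(a) < 1L || sum(b) < 1L) return(NA_real_)
    mean(lv[g, a]) - mean(lv[g, b])
  }, numeric(1))
  meanLog <- rowMeans(lmat)
  out <- data.frame(gene_id = rownames(m), mean_log = meanLog,
                    lfc_all = lfcAll, lfc_active = lfcActive,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$stratum <- .strataCut(out$mean_log, nBins)
  out
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same items, by
#' the standard pair-counting contingency formula. 1 for identical partitions
#' (up to relabeling), ~0 for independent ones.
#'
#' @param a,b partition labels of equal length (>= 2).
#' @return a number <= 1.
#' @examples
#' ari(c(1, 1, 2, 2), c(1, 2, 1, 2))  # -0.5
#' @export
ari <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have the same length")
  if (length(a) < 2L) stop("need at least 2 items")
  ct <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sumIJ <- sum(comb2(ct))
  sumA <- sum(comb2(rowSums(ct)))
  sumB <- sum(comb2(colSums(ct)))
  nPairs <- comb2(length(a))
  expected <- sumA * sumB / nPairs
  maxIdx <- (sumA + sumB) / 2
  if (maxIdx == expected) return(if (sumIJ == expected) 1 else 0)
  (sumIJ - expected) / (maxIdx - expected)
}

#' Cell-wise size-factor baseline normalization
#'
#' The trivial counts-per-total baseline: every count in a cell divided by
#' `L_i / L0` (library size over the reference library size), i.e. the same
#' factor for all genes in a cell. Provided as the contrast for the
#' non-linear factors; its over-adjustment of weakly depth-dependent genes is
#' what the two-phase method avoids.
#'
#' @param x count container accepted by the package.
#' @param ls optional [LibrarySizes-class].
#' @return genes x cells matrix of scaled values.
#' @export
cpmNormalize <- function(x, ls = NULL) {
  m <- .asCounts(x)
  ls <- ls %||% librarySizes(m)
  sweep(m, 2L, ls@L[colnames(m)] / ls@L0, "/")
}

#' Stability of group LFCs to cell removal
#'
#' Refits the supplied normalizer after dropping `k` cells (the ones with the
#' largest library sizes, or randomly chosen) and reports, per gene, the
#' change in the two-group log fold change - a robustness probe for
#' downstream differential expression.
#'
#' @param x count container accepted by the package.
#' @param groups two-group labels, length `ncol(x)`.
#' @param normalizer function(counts) returning a list with elements `mat`
#'   (normalized matrix) and `fit` (a [TwoPhaseFit-class]).
#' @param k number of cells to drop (default 5).
#' @param how `"largest"` (default) or `"random"`.
#' @param seed RNG seed for `how = "random"`.
#' @return data.frame: `gene_id`, `lfc_full`, `lfc_dropped`, `delta`.
#' @export
lfcStability <- function(x, groups, normalizer, k = 5L,
                         how = c("largest", "random"), seed = 1L) {
  how <- match.arg(how)
  m <- .asCounts(x)
  groups <- as.factor(groups)
  L <- colSums(m)
  drop_ <- if (how == "largest") {
    order(L, decreasing = TRUE)[seq_len(k)]
  } else {
    set.seed(seed)
    sample(ncol(m), k)
  }
  full <- normalizer(m)
  sub <- normalizer(m[, -drop_, drop = FALSE])
  lfcF <- groupLFC(full$mat, groups, full$fit)
  lfcS <- groupLFC(sub$mat, droplevels(groups[-drop_]), sub$fit)
  i <- match(lfcF$gene_id, lfcS$gene_id)
  data.frame(gene_id = lfcF$gene_id,
             lfc_full = lfcF$lfc_active,
             lfc_dropped = lfcS$lfc_active[i],
             delta = lfcS$lfc_active[i] - lfcF$lfc_active,
             stringsAsFactors = FALSE)
}
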
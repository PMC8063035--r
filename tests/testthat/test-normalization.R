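# Residuals, robust spline bias curves, log S evaluation, the reference
# constraint, and normalization application.

# a hand-built fit with exact parameters, for unit-level checks
mkFit <- function(m, mu, Zpost, estimable = rep(TRUE, nrow(m))) {
  n <- ncol(m)
  bg <- new("BackgroundParams", cellIds = colnames(m),
            p0 = rep(0.3, n), lambda = rep(1, n), nBgHat = rep(10, n),
            flagged = rep(FALSE, n), librarySize = unname(colSums(m)),
            yMax = 10L)
  new("TwoPhaseFit", geneIds = rownames(m), cellIds = colnames(m),
      mu = mu, sigma2 = rep(0.1, nrow(m)), piActive = rep(0.5, nrow(m)),
      estimable = estimable, Zpost = Zpost, loglikTrace = -1,
      nIter = 1L, converged = TRUE, background = bg)
}

test_that("residuals are log count minus gene mean on the active set only", {
  m <- countMat(c(20, 3, 7, 40, 1, 7), nr = 3)
  mu <- c(log(20), log(3), log(7))
  Z <- matrix(c(1, 1, 0.5, 1, 0.3, 0.5), 3, 2, dimnames = dimnames(m))
  fit <- mkFit(m, mu, Z)
  res <- computeResiduals(m, fit)
  # gene 3 (Z = 0.5 everywhere) contributes nothing at threshold 0.99
  expect_false("g3" %in% res$gene_id)
  # exact count at e^mu gives residual zero
  expect_equal(res$eps[res$gene_id == "g1" & res$cell_id == "c1"], 0)
  expect_equal(res$eps[res$gene_id == "g1" & res$cell_id == "c2"],
               log(40) - log(20))
  # unestimable genes are excluded
  fit2 <- mkFit(m, mu, Z, estimable = c(FALSE, TRUE, TRUE))
  expect_false("g1" %in% computeResiduals(m, fit2)$gene_id)
})

resTable <- function(x, eps, cell = "c1") {
  data.frame(gene_id = sprintf("g%d", seq_along(x)), cell_id = cell,
             mu = x, log_y = x + eps, eps = eps, stringsAsFactors = FALSE)
}

test_that("cell curves recover constants, lines and smooth functions", {
  # constant residuals -> constant curve, also in the extrapolation region
  rc <- resTable(runif(100, 2, 8), rep(0.37, 100))
  cv <- fitCellCurve(rc, "c1")
  expect_equal(evalCurve(cv, c(0, 3, 5, 12)), rep(0.37, 4), tolerance = 1e-9)

  # noiseless linear trend is inside the spline space
  set.seed(21)
  x <- c(2, 8, runif(398, 2, 8))
  rl <- resTable(x, 0.1 * x + 0.2)
  cvl <- fitCellCurve(rl, "c1")
  g <- seq(2, 8, length.out = 50)
  expect_lt(max(abs(evalCurve(cvl, g) - (0.1 * g + 0.2))), 1e-3)
  # constant extrapolation beyond the fitted range
  expect_equal(evalCurve(cvl, 100), evalCurve(cvl, max(x)))

  # smooth nonlinear signal under noise, over several seeds
  for (s in 1:5) {
    set.seed(200 + s)
    xs <- runif(2000, 0, 2 * pi)
    rs <- resTable(xs, sin(xs) / 2 + rnorm(2000, 0, 0.1))
    cvs <- fitCellCurve(rs, "c1")
    gg <- seq(quantile(xs, 0.05), quantile(xs, 0.95), length.out = 101)
    expect_lte(max(abs(evalCurve(cvs, gg) - sin(gg) / 2)), 0.1)
  }
})

test_that("curve fitting degrades gracefully with few points", {
  # below minCurvePoints: constant at the median
  r <- resTable(runif(30, 2, 6), c(rep(0.2, 29), 9))
  cv <- fitCellCurve(r, "c1")
  expect_identical(cv$type, "constant")
  expect_equal(cv$value, 0.2)
  # below minConstPoints: no curve; the caller uses the cohort median
  expect_null(fitCellCurve(resTable(1:5, rep(0, 5)), "c1"))
  # df capped at points - 1 with a warning
  r2 <- resTable(seq(2, 6, length.out = 60), rnorm(60, 0, 0.01))
  expect_warning(fitCellCurve(r2, "c1", df = 60L), "df reduced")
})

test_that("log S evaluation masks background entries and honours both modes", {
  m <- countMat(c(20, 3, 0, 40, 1, 7), nr = 3)
  mu <- c(log(20), log(3), log(7))
  Z <- matrix(c(1, 1, 0, 1, 0, 1), 3, 2, dimnames = dimnames(m))
  fit <- mkFit(m, mu, Z)
  active <- phaseCall(fit)
  flat <- list(type = "constant", value = 0, xr = c(0, 10))
  curves <- list(c1 = flat, c2 = flat)
  nf0 <- evalLogS(curves, m, active, fit = fit)
  expect_true(all(nf0@logS[!is.na(nf0@logS)] == 0))
  # zero count is masked even though its posterior is high
  expect_true(is.na(nf0@logS["g3", "c1"]))

  cc <- list(type = "constant", value = 0.7, xr = c(0, 10))
  nfa <- evalLogS(list(c1 = cc, c2 = cc), m, active, mode = "at_mu",
                  fit = fit)
  nfb <- evalLogS(list(c1 = cc, c2 = cc), m, active, mode = "at_count",
                  fit = fit)
  expect_equal(nfa@logS, nfb@logS)  # constant curves: modes agree
  expect_equal(unique(nfa@logS[!is.na(nfa@logS)]), 0.7)
})

test_that("reference rescaling enforces mean S = 1 and is idempotent", {
  m <- countMat(c(20, 30, 40, 20, 30, 40), nr = 3)
  mu <- log(c(20, 30, 40))
  Z <- matrix(1, 3, 2, dimnames = dimnames(m))
  fit <- mkFit(m, mu, Z)
  cc <- list(type = "constant", value = log(2), xr = c(0, 10))
  nf <- evalLogS(list(c1 = cc, c2 = cc), m, phaseCall(fit), fit = fit)
  ls <- librarySizes(m)
  r1 <- rescaleToReference(nf, ls)
  ref <- r1@referenceCell
  expect_lt(abs(mean(exp(r1@logS[, ref]), na.rm = TRUE) - 1), 1e-8)
  # S was 2 everywhere; after the constraint it is 1 everywhere
  expect_equal(unique(r1@logS[!is.na(r1@logS)]), 0)
  # idempotence: applying twice equals applying once
  r2 <- rescaleToReference(r1, ls)
  expect_equal(r2@logS, r1@logS)
  # the serialized curves track the shift
  expect_equal(evalCurve(r1@curves$c1, 3), 0)
})

test_that("normalization factors act as offsets or adjusted counts", {
  m <- countMat(c(10, 0, 8, 6), nr = 2)
  lS <- matrix(c(log(2), NA, 0, NA), 2, 2, dimnames = dimnames(m))
  nf <- new("NormFactorMatrix", geneIds = rownames(m), cellIds = colnames(m),
            logS = lS, curves = list(c1 = NULL, c2 = NULL),
            referenceCell = "c1", nActive = c(1L, 1L),
            curveFallback = c("none", "none"), rescaled = TRUE)
  expect_identical(applyNormFactors(m, nf, "offset"), lS)
  adj <- applyNormFactors(m, nf, "adjusted")
  expect_equal(adj["g1", "c1"], 5)        # Y = 10, S = 2
  expect_equal(adj["g1", "c2"], 8)        # S = 1
  expect_equal(adj["g2", "c1"], 0)        # masked zero untouched
  expect_equal(adj["g2", "c2"], 6)        # masked count untouched
  expect_identical(attr(adj, "recommendedGenes"), character(0))
  expect_identical(recommendedGenes(nf, 1L), "g1")

  # S identically 1: adjusted equals raw bit for bit
  nf1 <- nf
  nf1@logS <- matrix(0, 2, 2, dimnames = dimnames(m))
  adj1 <- applyNormFactors(m, nf1, "adjusted")
  attr(adj1, "recommendedGenes") <- NULL
  storage.mode(adj1) <- "integer"
  expect_identical(adj1, m)
})

test_that("pure cell-wise scaling yields near-constant curves recovering s_i", {
  cw <- fx("cellwise_bias")
  fit <- fxFit("cellwise_bias")
  nf <- fxNorm("cellwise_bias")
  tr <- simTruth(cw)
  res <- computeResiduals(cw, fit)
  sTrue <- exp(tr$logS[1, ])                 # same factor for all genes
  sRef <- sTrue[referenceCell(nf)]
  for (cid in colnames(simCounts(cw))) {
    xs <- res$mu[res$cell_id == cid]
    g <- seq(quantile(xs, 0.05), quantile(xs, 0.95), length.out = 101)
    f <- evalCurve(biasCurves(nf)[[cid]], g)
    expect_lte(diff(range(f)), 0.05)
    expect_lt(abs(exp(median(f)) - sTrue[cid] / sRef) / (sTrue[cid] / sRef),
              0.05)
  }
})

test_that("adjusted mode never alters masked background counts", {
  sim <- cached("pz_small",
                simulateTwoPhase(nGenes = 80, nCells = 30, piZeroFrac = 0.25,
                                 seed = 92))
  fit <- cached("pz_small_fit", fitTwoPhase(sim))
  nf <- estimateNormFactors(sim, fit, minCurvePoints = 20)
  m <- simCounts(sim)
  adj <- applyNormFactors(sim, nf, "adjusted")
  masked <- is.na(logS(nf))
  expect_identical(unname(adj[masked]), unname(as.numeric(m[masked])))
})
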
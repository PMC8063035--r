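# Count-depth statistics, MA tables, SD ratios, group LFCs and ARI.

test_that("a gene proportional to library size has slope and correlation near 1", {
  set.seed(41)
  n <- 200
  Lbase <- round(exp(runif(n, 9, 11)))
  m <- rbind(
    g1 = pmax(round(0.002 * Lbase), 16L),
    g2 = as.integer(Lbase)
  )
  colnames(m) <- sprintf("c%d", 1:n)
  storage.mode(m) <- "integer"
  cd <- countDepth(m, minMeanLog = 0)
  r1 <- cd[cd$gene_id == "g1", ]
  expect_gt(r1$correlation, 0.99)
  expect_lt(abs(r1$slope - 1), 0.05)
})

test_that("a depth-independent gene shows negligible correlation, and constants are NA", {
  set.seed(42)
  n <- 200
  m <- rbind(
    g1 = rpois(n, 30),                          # independent of L
    g2 = as.integer(round(exp(runif(n, 8, 10)))),
    g3 = rep(7L, n)                             # constant
  )
  colnames(m) <- sprintf("c%d", 1:n)
  cd <- countDepth(m, minMeanLog = 0)
  expect_lte(abs(cd$correlation[cd$gene_id == "g1"]), 0.15)
  expect_true(is.na(cd$correlation[cd$gene_id == "g3"]))
  expect_error(countDepth(m[, 1:2, drop = FALSE]), "3 cells")
})

test_that("the mean-log filter excludes weak genes by default", {
  set.seed(43)
  m <- rbind(g1 = rpois(50, 1), g2 = rpois(50, 400))
  colnames(m) <- sprintf("c%d", 1:50)
  cd <- countDepth(m)        # mean log2 filter at 4
  expect_identical(cd$gene_id, "g2")
})

test_that("MA tables carry phase labels and centre on the gene mean", {
  m <- countMat(c(20, 3, 7, 40, 1, 7), nr = 3)
  mu <- c(log(20), log(3), log(7))
  n <- ncol(m)
  bg <- new("BackgroundParams", cellIds = colnames(m),
            p0 = rep(0.3, n), lambda = rep(1, n), nBgHat = rep(10, n),
            flagged = rep(FALSE, n), librarySize = unname(colSums(m)),
            yMax = 10L)
  fit <- new("TwoPhaseFit", geneIds = rownames(m), cellIds = colnames(m),
             mu = mu, sigma2 = rep(0.1, 3), piActive = rep(0.5, 3),
             estimable = c(TRUE, TRUE, FALSE),
             Zpost = matrix(c(1, 0.2, 1, 1, 0.2, 1), 3, 2,
                            dimnames = dimnames(m)),
             loglikTrace = -1, nIter = 1L, converged = TRUE, background = bg)
  ma <- maData(m, fit, "c1")
  expect_setequal(ma$gene_id, c("g1", "g2"))  # unestimable g3 excluded
  expect_equal(ma$log_ratio[ma$gene_id == "g1"], 0)  # Y = e^mu
  expect_identical(ma$phase[ma$gene_id == "g1"], "active")
  expect_identical(ma$phase[ma$gene_id == "g2"], "background")
  expect_equal(ma$mean_log, mu[1:2])
  ma2 <- maData(m, fit, "c1", base = 2)
  expect_equal(ma2$mean_log, mu[1:2] / log(2))
})

test_that("conditional SD ratios are 1 when nothing changes, and filter sparse genes", {
  set.seed(44)
  m <- countMat(rpois(40 * 10, 50), nr = 40)
  Z <- matrix(1, 40, 10, dimnames = dimnames(m))
  Z[1, ] <- 0  # gene active nowhere
  Z[2, 3:10] <- 0  # active in only 2 cells
  n <- ncol(m)
  bg <- new("BackgroundParams", cellIds = colnames(m),
            p0 = rep(0.3, n), lambda = rep(1, n), nBgHat = rep(10, n),
            flagged = rep(FALSE, n), librarySize = unname(colSums(m)),
            yMax = 10L)
  fit <- new("TwoPhaseFit", geneIds = rownames(m), cellIds = colnames(m),
             mu = rep(log(50), 40), sigma2 = rep(0.1, 40),
             piActive = rep(0.9, 40), estimable = rep(TRUE, 40),
             Zpost = Z, loglikTrace = -1, nIter = 1L, converged = TRUE,
             background = bg)
  sdr <- conditionalSDRatio(m, m, fit)
  expect_true(all(sdr$ratio == 1))
  expect_false(any(c("g1", "g2") %in% sdr$gene_id))
  expect_true(all(table(sdr$stratum) >= 1))
  # rerunning yields a bit-identical table
  expect_identical(sdr, conditionalSDRatio(m, m, fit))
})

test_that("group LFCs vanish for mirrored groups and reject bad designs", {
  set.seed(45)
  half <- matrix(rpois(30 * 6, 40), nrow = 30)
  m <- cbind(half, half)
  rownames(m) <- sprintf("g%d", 1:30)
  colnames(m) <- sprintf("c%d", 1:12)
  groups <- rep(c("a", "b"), each = 6)
  n <- ncol(m)
  bg <- new("BackgroundParams", cellIds = colnames(m),
            p0 = rep(0.3, n), lambda = rep(1, n), nBgHat = rep(10, n),
            flagged = rep(FALSE, n), librarySize = unname(colSums(m)),
            yMax = 10L)
  fit <- new("TwoPhaseFit", geneIds = rownames(m), cellIds = colnames(m),
             mu = rep(log(40), 30), sigma2 = rep(0.1, 30),
             piActive = rep(0.9, 30), estimable = rep(TRUE, 30),
             Zpost = matrix(1, 30, n, dimnames = dimnames(m)),
             loglikTrace = -1, nIter = 1L, converged = TRUE, background = bg)
  lfc <- groupLFC(m, groups, fit)
  expect_true(all(lfc$lfc_all == 0))
  expect_true(all(lfc$lfc_active == 0))
  expect_error(groupLFC(m, rep(c("a", "b", "c"), 4), fit), "pairwise")
  expect_error(groupLFC(m, rep(c("a", "b"), c(10, 2)), fit), "3 cells")
})

test_that("adjusted Rand index matches the pair-counting oracle", {
  # brute force over all pairs: ARI = (agree - expected) / (max - expected)
  bruteARI <- function(a, b) {
    n <- length(a)
    sameA <- outer(a, a, "==")[upper.tri(diag(n))]
    sameB <- outer(b, b, "==")[upper.tri(diag(n))]
    s11 <- sum(sameA & sameB); sA <- sum(sameA); sB <- sum(sameB)
    np <- n * (n - 1) / 2
    exp_ <- sA * sB / np
    (s11 - exp_) / ((sA + sB) / 2 - exp_)
  }
  expect_equal(ari(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  expect_equal(ari(c(1, 1, 2, 2), c(1, 2, 1, 2)),
               bruteARI(c(1, 1, 2, 2), c(1, 2, 1, 2)))
  expect_equal(ari(letters[1:6], rep("x", 6)), 0)
  expect_equal(ari(1:6, 1:6), 1)
  expect_equal(ari(c(1, 1, 2, 2), c(4, 4, 9, 9)), 1)  # relabeling
  set.seed(46)
  for (i in 1:10) {
    a <- sample(1:3, 12, replace = TRUE)
    b <- sample(1:4, 12, replace = TRUE)
    expect_equal(ari(a, b), bruteARI(a, b))
  }
  expect_error(ari(1:3, 1:4), "length")
})

test_that("adjusted Rand index agrees with an independent implementation", {
  skip_if_not_installed("mclust")
  set.seed(47)
  for (i in 1:10) {
    a <- sample(1:3, 20, replace = TRUE)
    b <- sample(1:5, 20, replace = TRUE)
    expect_equal(ari(a, b), mclust::adjustedRandIndex(a, b))
  }
})

test_that("the size-factor baseline scales every gene by the cell factor", {
  m <- countMat(c(10, 20, 20, 40, 40, 80), nr = 2)
  ls <- librarySizes(m)
  cpm <- cpmNormalize(m, ls)
  expect_equal(cpm[, ls@referenceCell],
               as.numeric(m[, ls@referenceCell]), ignore_attr = TRUE)
  expect_equal(unname(colSums(cpm)), rep(ls@L0, 3))
})
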
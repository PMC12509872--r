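# Mean imputation, standardization, per-window PCA (hard-call and
# genotype-likelihood paths) and the scan driver.

test_that("mean imputation fills column means and drops empty columns", {
  g <- rbind(c(0, 1, 2), c(2, 0, 1))
  expect_identical(meanImpute(g)[, ], g)
  g2 <- rbind(c(0, NA), c(2, 1), c(NA, 1))
  out <- meanImpute(g2)
  expect_equal(out[3, 1], 1)  # mean of 0 and 2
  expect_equal(out[1, 2], 1)
  g3 <- matrix(c(0, 1, 2, NA, NA, NA, 1, 1, 1, 0, 2, 1), 3, 4)
  out3 <- meanImpute(g3)
  expect_equal(dim(out3), c(3, 3))
  expect_equal(attr(out3, "nDropped"), 1L)
})

test_that("standardization centers, patterson-scales and drops monomorphs", {
  g <- cbind(c(0, 1, 2))
  # p = 0.5: centered (-1, 0, 1), divided by sqrt(0.25) = 0.5
  expect_equal(unname(standardizeDosage(g, "patterson")[, 1]), c(-2, 0, 2))
  set.seed(1)
  r <- matrix(rbinom(50, 2, 0.4), 5, 10)
  cent <- standardizeDosage(r, "center")
  expect_equal(max(abs(colSums(cent))), 0, tolerance = 1e-12)
  mono <- cbind(c(2, 2, 2), c(0, 1, 2))
  out <- standardizeDosage(mono, "patterson")
  expect_equal(ncol(out), 1)
  expect_equal(attr(out, "nDropped"), 1L)
})

test_that("two identical groups produce equal-within, opposite-sign PC1", {
  g <- rbind(
    matrix(rep(c(0, 0, 2, 2), 3), 3, 4, byrow = TRUE),
    matrix(rep(c(2, 2, 0, 0), 3), 3, 4, byrow = TRUE)
  )
  res <- pcaWindow(g, scanParams(minVariants = 2, pcs = 1))
  s <- res$scores[, 1]
  expect_equal(sd(s[1:3]), 0, tolerance = 1e-10)
  expect_equal(sd(s[4:6]), 0, tolerance = 1e-10)
  expect_lt(s[1] * s[4], 0)
  expect_equal(sum(s), 0, tolerance = 1e-8)
})

test_that("window scores match an independent dense-decomposition oracle", {
  set.seed(20)
  for (i in 1:10) {
    ns <- sample(4:12, 1)
    nv <- sample(10:40, 1)
    g <- matrix(rbinom(ns * nv, 2, runif(1, 0.2, 0.8)), ns, nv)
    params <- scanParams(minVariants = 2, pcs = 1:2)
    res <- pcaWindow(g, params)
    if (!res$valid) next
    want <- oracleScores(g, pcs = 1:2)
    expectScoresEqualUpToSign(res$scores, want, tol = 1e-8)
    expect_equal(sum(res$scores[, 1]), 0, tolerance = 1e-8)
    expect_true(all(diff(res$varExplained) <= 1e-12))
  }
})

test_that("windows below the variant threshold are invalid with NA scores", {
  g <- structuredMatrix(4, 19)
  res <- pcaWindow(g, scanParams(minVariants = 20))
  expect_false(res$valid)
  expect_true(all(is.na(res$scores)))
  expect_error(pcaWindow(g[1, , drop = FALSE], scanParams()), "2 samples")
})

test_that("expected genotypes follow the Bayes posterior under a HWE prior", {
  certain <- array(0, c(1, 1, 3)); certain[1, 1, 3] <- 1
  expect_equal(expectedGenotypes(certain, 0.123)[1, 1], 2)
  flat <- array(1 / 3, c(1, 4, 3))
  p <- c(0.1, 0.3, 0.5, 0.9)
  expect_equal(unname(expectedGenotypes(flat, p)[1, ]), 2 * p,
               tolerance = 1e-12)
  # hand Bayes: (0.1, 0.8, 0.1) with p = 0.5 -> posterior prop. to
  # (0.1*0.25, 0.8*0.5, 0.1*0.25) -> E[g] = 1
  trip <- array(c(0.1, 0.8, 0.1), c(1, 1, 3))
  expect_equal(expectedGenotypes(trip, 0.5)[1, 1], 1, tolerance = 1e-12)
})

test_that("certain likelihoods make the GL path equal the GT path", {
  g <- structuredMatrix(5, 30, seed = 9)
  lik <- array(0, c(nrow(g), ncol(g), 3))
  for (i in seq_len(nrow(g))) {
    for (j in seq_len(ncol(g))) lik[i, j, g[i, j] + 1] <- 1
  }
  params <- scanParams(minVariants = 2, pcs = 1:2)
  gt <- pcaWindow(g, params)
  gl <- glPcaWindow(lik, params)
  expect_true(gl$converged)
  expect_equal(gl$scores, gt$scores, tolerance = 1e-6)
  expect_equal(gl$varExplained, gt$varExplained, tolerance = 1e-6)
})

test_that("an uninformative sample lands between the population clusters", {
  g <- structuredMatrix(5, 40, seed = 13)
  lik <- array(0, c(10, 40, 3))
  for (i in 1:10) {
    for (j in 1:40) lik[i, j, g[i, j] + 1] <- 1
  }
  lik[3, , ] <- 1 / 3  # an all-flat (no data) sample in group A
  res <- glPcaWindow(lik, scanParams(minVariants = 2, pcs = 1))
  s <- res$scores[, 1]
  mA <- mean(s[setdiff(1:5, 3)])
  mB <- mean(s[6:10])
  expect_gt(s[3], min(mA, mB))
  expect_lt(s[3], max(mA, mB))
})

test_that("deeper simulated likelihoods track the true-genotype PCA better", {
  sim <- simulateCohort(nSamplesPerPop = 15, chromLength = 6e4, seed = 21,
                        inversion = NULL)
  g <- sim$dosage
  params <- scanParams(minVariants = 2, pcs = 1)
  truthScores <- pcaWindow(g, params)$scores[, 1]
  set.seed(77)
  cors <- vapply(c(2, 8, 30), function(depth) {
    likFlat <- simulateLikelihoods(as.vector(g), depth, 0.01)
    lik <- array(NA_real_, c(nrow(g), ncol(g), 3))
    for (k in 1:3) lik[, , k] <- matrix(likFlat[, k], nrow(g), ncol(g))
    glScores <- glPcaWindow(lik, params)$scores[, 1]
    abs(cor(glScores, truthScores))
  }, numeric(1))
  expect_true(all(diff(cors) >= -1e-6))
  expect_gt(cors[3], 0.99)
})

test_that("the scan driver emits ordered windows matching isolated calls", {
  sim <- simulateCohort(nSamplesPerPop = 8, chromLength = 5e5, seed = 31,
                        inversion = NULL,
                        outPrefix = file.path(tempdir(), "drv"))
  params <- scanParams(windowSize = 1e5, stepSize = 2e4, minVariants = 10)
  vs <- readVariants(sim$paths["tsv"], "tsv", "chr1")
  track <- runWindowedPCA(vs, params, chromSpan = 5e5, polarize = FALSE)
  expect_equal(nrow(track), windowCount(5e5, 1e5, 2e4))
  expect_s4_class(track, "PCTrack")
  specs <- windowSpecs("chr1", 5e5, 1e5, 2e4)
  mem <- windowMembership(vs@pos, specs)
  for (w in c(1, 5, 10)) {
    iso <- pcaWindow(vs@dosage[, mem[[w]], drop = FALSE], params)
    if (!iso$valid) next
    expectScoresEqualUpToSign(
      cbind(pcScores(track, 1)[w, ]), cbind(iso$scores[, 1]), tol = 1e-10
    )
  }
  # per-PC scores sum to zero on every valid window
  for (k in 1:2) {
    m <- pcScores(track, k)[validWindows(track), , drop = FALSE]
    expect_equal(max(abs(rowSums(m))), 0, tolerance = 1e-6)
  }
})

test_that("a synthetic 5 Mbp chromosome yields the window-formula count", {
  specs <- windowSpecs("chr1", 5e6, 1e6, 1e5)
  expect_equal(nrow(specs), 41)
  expect_equal(windowCount(5e6, 1e6, 1e5), 41L)
})

test_that("a track with every window under threshold warns and is invalid", {
  sim <- simulateCohort(nSamplesPerPop = 4, chromLength = 1e5, seed = 41,
                        variantDensity = 1 / 5000, inversion = NULL)
  vs <- new("VariantSet", chrom = "chr1", pos = as.numeric(sim$pos),
            ref = sim$ref, alt = sim$alt, sampleIds = sim$sampleIds,
            dosage = sim$observed,
            likelihoods = array(numeric(), c(0, 0, 0)), skipped = integer())
  params <- scanParams(windowSize = 2e4, stepSize = 2e4, minVariants = 50)
  expect_warning(track <- runWindowedPCA(vs, params, chromSpan = 1e5),
                 "minVariants")
  expect_false(any(validWindows(track)))
  expect_true(all(is.na(pcScores(track, 1))))
})
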
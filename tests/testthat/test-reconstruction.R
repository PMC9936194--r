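# Percentile scores, SCR/MCR identities, unflattening and export.

# a small hand-made model with controllable scores
mkModel <- function(center, loadings, scores, kind = "") {
  methods::new("WaveformPca", center = center, loadings = loadings,
               scores = scores,
               varExplained = rep(1 / ncol(loadings), ncol(loadings)),
               kind = kind)
}

test_that("score percentiles match an independent quantile oracle", {
  m <- mkModel(numeric(2), cbind(c(0.6, 0.8)), matrix(1:100, 100, 1))
  expect_equal(scorePercentile(m, 1, 0.95), quantileOracle(1:100, 0.95))
  expect_equal(scorePercentile(m, 1, 0), 1)       # q = 0 is the minimum
  sym <- mkModel(numeric(2), cbind(c(1, 0)), matrix(c(-3, -1, 1, 3), 4, 1))
  expect_equal(scorePercentile(sym, 1, 0.5), 0, tolerance = 1e-12)
  expect_error(scorePercentile(m, 5, 0.5), "out of range")
})

test_that("SCR follows the mean-plus-scaled-loading arithmetic", {
  m <- mkModel(c(1, 1), cbind(c(0.6, 0.8)), matrix(2, 5, 1))
  pair <- scr(m, 1, qHi = 0.95, qLo = 0.05)  # all scores are 2
  expect_equal(pair@upper, c(2.2, 2.6))
  expect_equal(pair@lower, c(2.2, 2.6))
  # zero scores collapse both bounds onto the mean
  z <- mkModel(c(1, 1), cbind(c(0.6, 0.8)), matrix(0, 5, 1))
  pz <- scr(z, 1)
  expect_equal(pz@upper, z@center)
  expect_equal(pz@lower, z@center)
})

test_that("SCR deviations are collinear with the loading", {
  set.seed(17)
  L <- qr.Q(qr(matrix(rnorm(40), 10, 4)))
  m <- mkModel(rnorm(10), L, matrix(rnorm(120), 30, 4))
  pair <- scr(m, 2)
  dev <- pair@upper - pair@center
  # projection onto the loading explains the whole deviation
  resid <- dev - sum(dev * L[, 2L]) * L[, 2L]
  expect_lt(max(abs(resid)), 1e-12)
})

test_that("MCR reduces to SCR for one component and adds linearly", {
  set.seed(18)
  L <- qr.Q(qr(matrix(rnorm(60), 12, 5)))
  m <- mkModel(rnorm(12), L, matrix(rnorm(100), 20, 5))
  p1 <- mcr(m, 3)
  s1 <- scr(m, 3)
  expect_equal(p1@upper, s1@upper)
  expect_equal(p1@lower, s1@lower)
  # two components: deviation equals the sum of individual deviations
  p12 <- mcr(m, c(1, 4))
  d <- (scr(m, 1)@upper - m@center) + (scr(m, 4)@upper - m@center)
  expect_equal(p12@upper - m@center, d, tolerance = 1e-12)
  expect_error(mcr(m, integer()), "at least one")
})

test_that("outcome alignment flips only negative-coefficient components", {
  set.seed(19)
  L <- qr.Q(qr(matrix(rnorm(30), 10, 3)))
  scores <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, paste0("PC", 1:3)))
  m <- mkModel(rnorm(10), L, scores)
  y <- 2 * scores[, 1L] - 1.5 * scores[, 2L] + rnorm(20, sd = 0.1)
  reg <- stepwiseRegress(scores[, 1:2], y)
  # all-positive coefficients: alignment is a no-op
  regPos <- stepwiseRegress(scores[, 1L, drop = FALSE], 2 * scores[, 1L])
  pA <- mcr(m, 1, regression = regPos, alignToOutcome = TRUE)
  pB <- mcr(m, 1)
  expect_equal(pA@upper, pB@upper)
  # with a negative PC2 coefficient the upper bound must maximize the
  # predicted outcome
  pr <- mcr(m, c(1, 2), regression = reg, alignToOutcome = TRUE)
  tt <- modelTerms(reg)
  b <- tt$estimate[match(paste0("PC", 1:2), tt$term)]
  predUp <- sum(b * pr@zUpper)
  predLo <- sum(b * pr@zLower)
  expect_gt(predUp, predLo)
  # and per component the aligned upper z is the velocity-increasing one
  expect_equal(pr@zUpper[2L], scorePercentile(m, 2, 0.05))
  expect_error(mcr(m, 1, alignToOutcome = TRUE), "regression")
})

test_that("a subject is reproduced from its own full score set", {
  set.seed(20)
  X <- matrix(rnorm(8 * 50), 8, 50)
  p <- fitWaveformPca(X)
  rec <- reconstructFeatures(p, pcaScores(p)[3L, ])
  expect_equal(as.vector(rec), X[3L, ], tolerance = 1e-8)
})

test_that("unflattening checks lengths and inverts both layouts", {
  expect_error(unflattenFeatures(numeric(19393)), "neither")
  expect_error(unflattenFeatures(numeric(10), "kinematic"), "19392")
  v <- rnorm(18000)
  m <- unflattenFeatures(v)
  expect_equal(dim(m), c(2000L, 9L))
  expect_equal(as.vector(m), v)
  expect_identical(colnames(m), emgChannels())
})

test_that("kinematic reconstructions export as readable C3D avatars", {
  set.seed(23)
  X <- matrix(rnorm(6 * 19392, sd = 0.05), 6, 19392)
  p <- fitWaveformPca(X)
  p@kind <- "kinematic"
  pair <- scr(p, 1)
  dir <- withr::local_tempdir()
  paths <- exportReconstruction(pair, dir, referenceHeight = 1.8)
  expect_length(list.files(dir, pattern = "\\.c3d$"), 3L)
  back <- readC3D(file.path(dir, "recon_mean.c3d"))
  expect_equal(dim(back$positions), c(101L, 64L, 3L))
  expect_equal(back$positions,
               unflattenFeatures(pair@center, "kinematic") * 1.8,
               tolerance = 1e-5, ignore_attr = TRUE)
})
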
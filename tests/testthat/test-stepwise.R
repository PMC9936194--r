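# Univariate screening and stepwise regression: exact recovery, null
# calibration, guards and refit consistency.

test_that("univariate screening finds perfect and null correlations", {
  set.seed(6)
  z <- matrix(rnorm(40 * 4), 40, 4, dimnames = list(NULL, paste0("PC", 1:4)))
  out <- univariateScreen(z, 2 * z[, 1L])
  expect_equal(out$r[1L], 1, tolerance = 1e-12)
  expect_lt(out$p[1L], 1e-20)

  # independent outcome, large n: |r| stays near the 1/sqrt(n) null scale
  set.seed(7)
  zBig <- matrix(rnorm(1000 * 5), 1000, 5)
  scr <- univariateScreen(zBig, rnorm(1000))
  expect_true(all(abs(scr$r) < 0.1))

  expect_error(univariateScreen(z, rep(3, 40)), "constant")
  zDeg <- cbind(z, PC5 = rep(1, 40))
  expect_error(univariateScreen(zDeg, rnorm(40)), "zero variance")
})

test_that("noiseless linear truth is recovered exactly", {
  set.seed(12)
  X <- matrix(rnorm(30 * 10), 30, 10,
              dimnames = list(NULL, paste0("x", 1:10)))
  y <- 2 * X[, 1L] - X[, 3L]
  m <- stepwiseRegress(X, y)
  expect_setequal(selectedTerms(m), c("x1", "x3"))
  tt <- modelTerms(m)
  expect_equal(tt$estimate[match("x1", tt$term)], 2, tolerance = 1e-8)
  expect_equal(tt$estimate[match("x3", tt$term)], -1, tolerance = 1e-8)
  expect_equal(m@r2, 1, tolerance = 1e-10)
})

test_that("null entry rate is consistent with the 5% entry threshold", {
  set.seed(2024)
  reps <- 1000L
  entered <- logical(reps)
  for (i in seq_len(reps)) {
    x <- matrix(rnorm(30), 30, 1, dimnames = list(NULL, "x1"))
    y <- rnorm(30)
    entered[i] <- length(selectedTerms(stepwiseRegress(x, y))) > 0L
  }
  expect_gt(mean(entered), 0.02)
  expect_lt(mean(entered), 0.08)
})

test_that("guards reject cycling thresholds and degenerate inputs", {
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  y <- rnorm(20)
  expect_error(stepwiseRegress(X, y, pEnter = 0.10, pRemove = 0.05),
               "cycling")
  expect_error(stepwiseRegress(X, y[1:5]), "length")
  expect_error(stepwiseRegress(unname(X), y), "column names")
})

test_that("pure-noise candidates can yield an intercept-only model", {
  set.seed(99)
  X <- matrix(rnorm(25 * 3), 25, 3, dimnames = list(NULL, paste0("n", 1:3)))
  y <- rnorm(25)
  m <- stepwiseRegress(X, y)
  # with this seed nothing clears the 5% threshold
  expect_length(selectedTerms(m), 0L)
  expect_equal(m@r2, 0)
  expect_equal(modelTerms(m)$estimate[1L], mean(y), tolerance = 1e-12)
})

test_that("reported estimates equal a direct refit of the selected terms", {
  set.seed(41)
  X <- matrix(rnorm(35 * 8), 35, 8, dimnames = list(NULL, paste0("x", 1:8)))
  y <- 1.5 * X[, 2L] + 0.8 * X[, 5L] + rnorm(35, sd = 0.3)
  m <- stepwiseRegress(X, y)
  sel <- selectedTerms(m)
  refit <- lm(y ~ ., data = as.data.frame(X[, sel, drop = FALSE]))
  cf <- summary(refit)$coefficients
  tt <- modelTerms(m)
  expect_equal(tt$estimate, unname(cf[, 1L]), tolerance = 1e-12)
  expect_equal(tt$se, unname(cf[, 2L]), tolerance = 1e-12)
  expect_equal(m@r2, summary(refit)$r.squared, tolerance = 1e-12)
  expect_equal(m@rmse, summary(refit)$sigma, tolerance = 1e-12)
  # R^2 identity: 1 - SSE/SST from the fitted values
  sse <- sum((y - fitted(m@fit))^2)
  sst <- sum((y - mean(y))^2)
  expect_equal(m@r2, 1 - sse / sst, tolerance = 1e-12)
})

test_that("backward elimination removes terms made redundant later", {
  # x3 = x1 + x2 + tiny noise; y depends on x1 and x2. Forward entry
  # may pick x3 first (best single predictor), after which x1/x2 enter
  # and x3 must be eliminated.
  set.seed(55)
  n <- 60
  x1 <- rnorm(n); x2 <- rnorm(n)
  x3 <- x1 + x2 + rnorm(n, sd = 0.01)
  X <- cbind(x1 = x1, x2 = x2, x3 = x3)
  y <- 2 * x1 - 3 * x2 + rnorm(n, sd = 0.05)
  m <- stepwiseRegress(X, y)
  expect_setequal(selectedTerms(m), c("x1", "x2"))
})

test_that("model reports round-trip through CSV", {
  set.seed(13)
  X <- matrix(rnorm(30 * 3), 30, 3, dimnames = list(NULL, paste0("x", 1:3)))
  y <- X[, 1L] + rnorm(30, sd = 0.2)
  m <- stepwiseRegress(X, y)
  path <- withr::local_tempfile(fileext = ".csv")
  writeModelReport(m, path)
  tab <- read.csv(path, check.names = FALSE)
  expect_equal(tab$Estimate, modelTerms(m)$estimate, tolerance = 1e-12)
  expect_equal(tab$R2[1L], m@r2, tolerance = 1e-12)
})
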
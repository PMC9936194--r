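# Linear envelope, filter contracts, residual analysis, amplitude
# normalization and EMG feature assembly.

emgOf <- function(sig, rate = 2000) {
  colnames(sig) <- emgChannels()
  emgTrial(sig, rate = rate)
}

test_that("dual-pass filter has unity DC gain and half gain at cutoff", {
  rate <- 2000
  # DC gain
  x <- rep(0.7, 4000)
  y <- dualPassFilter(x, rate, 250)
  expect_lt(max(abs(y - 0.7)), 1e-9)
  # amplitude ratio at the cutoff frequency: |H|^2 of a -3.01 dB
  # single pass is 0.501
  t <- (seq_len(8000) - 1) / rate
  s <- sin(2 * pi * 250 * t)
  ys <- dualPassFilter(s, rate, 250)
  core <- 1000:7000
  ratio <- fitSineAmplitude(ys[core], rate, 250)
  expect_equal(unname(ratio), 0.5012, tolerance = 0.01)
})

test_that("a slow rectified sinusoid passes through nearly unchanged", {
  rate <- 2000
  t <- (seq_len(6000) - 1) / rate
  x <- abs(sin(2 * pi * 2.5 * t))  # 0.01 * the 250 Hz cutoff
  y <- dualPassFilter(x, rate, 250)
  expect_lt(max(abs(y - x)), 0.01)
})

test_that("the envelope filter is zero-phase on a symmetric burst", {
  rate <- 2000
  t <- (seq_len(4000) - 1) / rate
  burst <- exp(-(t - 1)^2 / (2 * 0.03^2))
  y <- dualPassFilter(burst, rate, 30)
  expect_lte(abs(which.max(y) - which.max(burst)), 1)
})

test_that("linearEnvelope rectifies, is nonnegative, and rejects bad cutoffs", {
  set.seed(2)
  sig <- matrix(rnorm(4000 * 9), 4000, 9)
  emg <- emgOf(sig)
  env <- linearEnvelope(emg, 250)
  expect_true(all(emgSignal(env) >= 0))
  # constant channels pass through at DC gain 1
  csig <- matrix(0.4, 2000, 9)
  cenv <- linearEnvelope(emgOf(csig), 250)
  expect_lt(max(abs(emgSignal(cenv) - 0.4)), 1e-9)
  expect_error(linearEnvelope(emg, 1000), "Nyquist")
})

test_that("residual analysis picks the lowest cutoff for noiseless data", {
  rate <- 2000
  t <- (seq_len(8000) - 1) / rate
  env <- 0.5 + 0.4 * sin(2 * pi * 5 * t)
  sig <- matrix(env, length(env), 9)
  ra <- residualAnalysis(emgOf(sig), cutoffs = c(50, 100, 200, 300, 400, 500))
  expect_true(all(ra$cutoff == 50))
  expect_lt(max(ra$residuals[nrow(ra$residuals), ]), 1e-3)
  # infinite cutoff = no filtering = zero residual
  ra2 <- residualAnalysis(emgOf(sig), cutoffs = c(50, 100, 200, Inf))
  expect_equal(unname(ra2$residuals[4L, 1L]), 0)
  expect_error(residualAnalysis(emgOf(sig), cutoffs = c(50, 500)),
               "linear tail")
})

test_that("residual curve matches brute-force RMS and reacts to noise", {
  rate <- 2000
  set.seed(11)
  t <- (seq_len(8000) - 1) / rate
  base <- 0.5 + 0.4 * sin(2 * pi * 5 * t)
  sig <- matrix(base + rnorm(length(t), sd = 0.2), length(t), 9)
  cutoffs <- c(10, 25, 50, 100, 200, 400, 600, 800)
  ra <- residualAnalysis(emgOf(sig), cutoffs)
  # independent brute-force residual for one channel and one cutoff
  rect <- abs(sig[, 3L])
  filt <- dualPassFilter(rect, rate, 100)
  expect_equal(unname(ra$residuals[4L, 3L]),
               sqrt(mean((filt - rect)^2)), tolerance = 1e-12)
  # residuals decrease with cutoff, and the chosen cutoff sits inside
  # the candidate range, reproducibly
  expect_true(all(diff(ra$residuals[, 1L]) < 0))
  expect_true(all(ra$cutoff >= 10 & ra$cutoff <= 800))
  ra2 <- residualAnalysis(emgOf(sig), cutoffs)
  expect_identical(ra$cutoff, ra2$cutoff)
})

test_that("amplitude normalization divides by the mean of the top three peaks", {
  rate <- 2000
  n <- 2000L
  mkChannel <- function(peaks) {
    x <- rep(0, n)
    at <- seq(200, by = 300, length.out = length(peaks))
    for (i in seq_along(peaks)) {
      idx <- (at[i] - 50):(at[i] + 50)
      x[idx] <- x[idx] + peaks[i] * exp(-((idx - at[i])^2) / (2 * 15^2))
    }
    x
  }
  sig <- matrix(rep(mkChannel(c(4, 3, 2, 1)), 9), n, 9)
  norm <- amplitudeNormalize(emgOf(sig), n)
  # divisor = mean(4, 3, 2) = 3
  expect_equal(max(emgSignal(norm)[, 1L]), 4 / 3, tolerance = 1e-6)
  expect_true(isNormalized(norm))

  sig2 <- matrix(rep(mkChannel(c(2, 2, 2)), 9), n, 9)
  norm2 <- amplitudeNormalize(emgOf(sig2), n)
  expect_equal(max(emgSignal(norm2)[, 1L]), 1, tolerance = 1e-6)

  # doubling the raw amplitude leaves the normalized waveform unchanged
  norm3 <- amplitudeNormalize(emgOf(2 * sig), n)
  expect_equal(emgSignal(norm3), emgSignal(norm), tolerance = 1e-12)

  expect_error(amplitudeNormalize(emgOf(matrix(0, n, 9)), n), "peaks")
})

test_that("EMG feature assembly flattens channel-major to length 18000", {
  n <- 12000L
  set.seed(5)
  sig <- matrix(abs(rnorm(n * 9)), n, 9)
  emg <- emgOf(sig)
  w <- cbind(start = c(1, 2000, 4000, 6000, 8000),
             end = c(2000, 4000, 6000, 8000, 10000))
  v <- assembleEmgFeatures(emg, w)
  expect_length(v, 18000L)
  # five identical cycles equal a single flattened cycle (the window
  # endpoints are shared, so the content must be periodic)
  per <- sig[1:2001, ]
  per[2001L, ] <- per[1L, ]
  sig2 <- rbind(per[-2001, ], per[-2001, ], per[-2001, ], per[-2001, ],
                per)
  w2 <- cbind(start = c(0, 2000, 4000, 6000, 8000) + 1,
              end = c(2000, 4000, 6000, 8000, 10000) + 1)
  v2 <- assembleEmgFeatures(emgOf(sig2), w2)
  tOut <- seq(1, 2001, length.out = 2000)
  single <- apply(per, 2L, function(y) spline(1:2001, y, xout = tOut)$y)
  expect_equal(v2, as.vector(single), tolerance = 1e-9)
  # zero envelope gives the zero vector; out-of-range windows error
  expect_equal(assembleEmgFeatures(emgOf(matrix(0, n, 9)), w),
               rep(0, 18000L))
  expect_error(assembleEmgFeatures(emg, cbind(start = 1, end = n + 5)),
               "outside")
})

test_that("scaling the raw recording leaves normalized features unchanged", {
  fx <- registeredFixture()
  emg <- fx$raw$emg
  kin <- fx$reg$trial
  kf <- kinematicFeatures(kin)
  f1 <- emgFeatures(emg, kin, kf$windows)
  scaled <- emgTrial(emgSignal(emg) * 3.7, rate = trialRate(emg))
  f2 <- emgFeatures(scaled, kin, kf$windows)
  expect_equal(f2$features, f1$features, tolerance = 1e-9)
  expect_length(f1$features, 18000L)
})
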
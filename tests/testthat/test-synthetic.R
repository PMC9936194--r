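# The synthetic cohort generator: determinism, stride content, the
# velocity model, ground-truth rank, and downstream compatibility.

test_that("identical seeds give bit-identical trials and cohorts", {
  spec <- tinySpec()
  t1 <- generateTrial(2L, spec)
  t2 <- generateTrial(2L, spec)
  expect_identical(trialPositions(t1$marker), trialPositions(t2$marker))
  expect_identical(emgSignal(t1$emg), emgSignal(t2$emg))
  # different subject or seed changes the trial
  t3 <- generateTrial(3L, spec)
  expect_false(identical(trialPositions(t1$marker),
                         trialPositions(t3$marker)))
  t4 <- generateTrial(2L, spec, seed = 99L)
  expect_false(identical(trialPositions(t1$marker),
                         trialPositions(t4$marker)))
})

test_that("a 10 s sprint at 2 strides/s has at least 19 ankle minima", {
  # slow subject: duration = 63/vmax + tau + 0.5 > 10 s
  spec <- cohortSpec(nSubjects = 4, nModesKinematic = 0, nModesEmg = 0,
                     velocityIntercept = 7.0, sexEffect = 0,
                     noiseSdVelocity = 0, strideRateHz = 2,
                     trueCoefficients = data.frame(mode = integer(),
                                                   weight = numeric()),
                     modeScoreSd = numeric(), seed = 2)
  tr <- generateTrial(1L, spec, what = "kinematic")
  z <- trialPositions(tr$marker)[, match("RightAnkle", markerLabels()), 3L]
  expect_gte(length(z) / 60, 10)
  # brute-force scan for strict local minima of the raw signal
  n <- length(z)
  minima <- which(z[2:(n - 1)] < z[1:(n - 2)] & z[2:(n - 1)] < z[3:n]) + 1L
  expect_gte(length(minima), 19L)
})

test_that("the noise-free velocity model is exact in the cohort truth", {
  spec <- cohortSpec(nSubjects = 12, nModesKinematic = 2, nModesEmg = 0,
                     trueCoefficients = data.frame(mode = 1:2,
                                                   weight = c(0, 0)),
                     modeScoreSd = c(0.25, 0.18),
                     noiseSdVelocity = 0, sexEffect = 0.5,
                     velocityIntercept = 7.7, seed = 4)
  cohort <- generateCohort(spec, what = "kinematic")
  cov <- cohort$covariates
  # with zero-weight modes and zero noise, velocity is determined by sex
  expect_true(all(tapply(cov$peakVelocityTrue, cov$sex,
                         function(v) diff(range(v))) < 1e-12))
  expect_gt(length(unique(cov$sex)), 1)
  vF <- unique(cov$peakVelocityTrue[cov$sex == 0])
  vM <- unique(cov$peakVelocityTrue[cov$sex == 1])
  expect_equal(vM - vF, 0.5, tolerance = 1e-12)
  expect_equal(vF, 7.7, tolerance = 1e-12)
})

test_that("ground-truth feature offsets have rank at most the mode count", {
  spec <- tinySpec()
  cohort <- generateCohort(spec, what = "kinematic")
  off <- cohort$truth$featureOffsets
  sv <- svd(off)$d
  expect_lt(sv[spec@nModesKinematic + 1L], 1e-8)
  expect_gt(sv[spec@nModesKinematic], 1e-3)
  # mode waveforms are unit-norm and mutually orthogonal
  G <- crossprod(cohort$truth$modeWaveforms)
  expect_equal(G, diag(spec@nModesKinematic), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("generated trials satisfy every downstream precondition", {
  spec <- tinySpec()
  for (i in 1:2) {
    tr <- generateTrial(i, spec)
    reg <- registerSprint(tr$marker)        # needs > 60 m of travel
    kf <- kinematicFeatures(reg$trial)      # needs >= 6 stride events
    expect_length(kf$features, 19392L)
    expect_gte(length(kf$events), 7L)
    ef <- emgFeatures(tr$emg, reg$trial, kf$windows)
    expect_length(ef$features, 18000L)
    expect_true(isNormalized(ef$envelope))
  }
})

test_that("trials too short for five strides raise the dedicated error", {
  spec <- cohortSpec(nSubjects = 4, strideRateHz = 0.5, seed = 3)
  expect_error(generateTrial(1L, spec), class = "sprintmodesShortTrial")
})

test_that("invalid cohort specifications are rejected", {
  expect_error(cohortSpec(nSubjects = 2), "nSubjects")
  expect_error(cohortSpec(noiseSdVelocity = -1), "noiseSdVelocity")
  expect_error(cohortSpec(strideRateHz = 0), "strideRateHz")
  expect_error(cohortSpec(nModesKinematic = 1,
                          trueCoefficients = data.frame(mode = 3,
                                                        weight = 1),
                          modeScoreSd = 0.2), "not generated")
})
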
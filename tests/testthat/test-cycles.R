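# Speed profile, stride segmentation, cycle selection, time
# normalization and kinematic feature assembly.

test_that("speed is exact for constant-velocity motion in both modes", {
  trial <- constantSpeedTrial(speed = 8, duration = 3)
  for (mode in c("vector", "norm-derivative")) {
    sp <- speedProfile(trial, mode = mode)
    expect_equal(sp$speed, rep(8, length(sp$speed)), tolerance = 1e-9)
    expect_equal(sp$peakSpeed, 8, tolerance = 1e-9)
  }
  # stationary trunk
  still <- constantSpeedTrial(speed = 0, duration = 2)
  expect_equal(speedProfile(still)$speed,
               rep(0, dim(trialPositions(still))[1L]), tolerance = 1e-12)
})

test_that("vector-mode speed matches an independent numeric oracle", {
  rate <- 60
  t <- seq(0, 5, by = 1 / rate)
  nF <- length(t)
  pos <- array(0, dim = c(nF, 64L, 3L))
  i8 <- match("T8", markerLabels())
  pos[, i8, 1L] <- 5 * t
  pos[, i8, 3L] <- 0.1 * sin(2 * pi * 2 * t)
  trial <- markerTrial(pos, markerLabels(), rate)
  sp <- speedProfile(trial)

  # oracle: independent central differences on each axis, then the norm
  cd <- function(x) {
    n <- length(x)
    c(x[2] - x[1], (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1]) * rate
  }
  oracle <- sqrt(cd(pos[, i8, 1])^2 + cd(pos[, i8, 2])^2 +
                 cd(pos[, i8, 3])^2)
  expect_equal(sp$speed, oracle, tolerance = 1e-12)
  # and the analytic peak max||(5, 0, 0.4*pi*cos)|| to discretization error
  expect_equal(sp$peakSpeed, sqrt(25 + (0.4 * pi)^2), tolerance = 1e-2)
})

test_that("stride minima land on the troughs of a sinusoidal ankle", {
  rate <- 60
  t <- seq(0, 5 - 1 / rate, by = 1 / rate)
  nF <- length(t)
  pos <- array(0, dim = c(nF, 64L, 3L))
  ia <- match("RightAnkle", markerLabels())
  # phase offset keeps troughs away from exact half-frame positions,
  # where the minimum frame is genuinely ambiguous
  ph <- 0.3
  pos[, ia, 3L] <- 0.1 + 0.05 * sin(2 * pi * 2 * t + ph)
  trial <- markerTrial(pos, markerLabels(), rate)
  ev <- detectStrideMinima(trial)
  # analytic troughs where the sine argument is 3*pi/2 + 2*pi*k
  troughT <- (3 * pi / 2 - ph + 2 * pi * (0:9)) / (4 * pi)
  troughFrames <- round(troughT * rate) + 1
  troughFrames <- troughFrames[troughFrames > 1 & troughFrames < nF]
  expect_gte(length(ev), length(troughFrames) - 1)
  expect_lte(length(ev), length(troughFrames) + 1)
  matched <- vapply(ev, function(e) min(abs(e - troughFrames)), 0)
  expect_lte(max(matched), 2)

  # translation invariance and the monotone failure case
  pos2 <- pos; pos2[, , 3L] <- pos2[, , 3L] + 0.5
  expect_identical(detectStrideMinima(markerTrial(pos2, markerLabels(), rate)),
                   ev)
  pos3 <- pos; pos3[, ia, 3L] <- seq_len(nF) / nF
  expect_error(detectStrideMinima(markerTrial(pos3, markerLabels(), rate)),
               "too few strides")
})

test_that("five cycles are centered on the peak with boundary shifts", {
  events <- seq(10, 110, by = 10)  # 11 events, windows 1..10
  # peak inside window 5 ([50, 60)) -> windows 3..7
  w <- selectCyclesAboutPeak(events, 55)
  expect_equal(w[, "start"], events[3:7])
  expect_equal(w[, "end"], events[4:8])
  # peak in window 1 -> windows 1..5
  w1 <- selectCyclesAboutPeak(events, 12)
  expect_equal(w1[, "start"], events[1:5])
  # peak in last window -> windows 6..10
  w2 <- selectCyclesAboutPeak(events, 108)
  expect_equal(w2[, "start"], events[6:10])
  # exactly 6 events: the only possible block
  w3 <- selectCyclesAboutPeak(events[1:6], 35)
  expect_equal(w3[, "start"], events[1:5])
  expect_error(selectCyclesAboutPeak(events[1:5], 30), "at least 6")
})

test_that("time normalization reproduces knots, de-biases T12 and scales by height", {
  rate <- 60
  nF <- 200L
  labels <- markerLabels()
  pos <- array(0, dim = c(nF, 64L, 3L))
  for (m in 1:64) for (a in 1:3)
    pos[, m, a] <- 0.01 * m + 0.002 * a * seq_len(nF)  # linear ramps
  trial <- markerTrial(pos, labels, rate,
                       list(id = "t", height = 2, sex = 0, age = 20))
  # a window of exactly 101 frames: resampling lands on the original
  # frames, so values must match the originals (after de-bias/height)
  cyc <- normalizeCycle(trial, c(40L, 140L))
  i12 <- match("T12", labels)
  expect_equal(cyc[, i12, ], matrix(0, 101, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  m <- match("HeadTop", labels)
  manual <- (pos[40:140, m, 2L] - pos[40:140, i12, 2L]) / 2
  expect_equal(cyc[, m, 2L], manual, tolerance = 1e-9)
  expect_error(normalizeCycle(trial, c(40L, 140L), height = 0), "height")
  expect_error(normalizeCycle(trial, c(40L, 42L)), "at least 4")
})

test_that("spline resampling of a sine is accurate to 1e-3", {
  rate <- 60
  t <- seq(0, 1, by = 1 / rate)  # one period at 1 Hz
  nF <- length(t)
  labels <- markerLabels()
  pos <- array(0, dim = c(nF, 64L, 3L))
  m <- match("HeadTop", labels)
  pos[, m, 1L] <- sin(2 * pi * t)
  trial <- markerTrial(pos, labels, rate,
                       list(id = "s", height = 1, sex = 0, age = 20))
  cyc <- normalizeCycle(trial, c(1L, nF))
  tNorm <- seq(0, 1, length.out = 101)
  expect_lt(max(abs(cyc[, m, 1L] - sin(2 * pi * tNorm))), 1e-3)
})

test_that("feature assembly averages cycles and flattens to length 19392", {
  set.seed(3)
  c1 <- array(rnorm(101 * 64 * 3), dim = c(101L, 64L, 3L))
  v <- assembleKinematicFeatures(list(c1, c1, c1, c1, c1))
  expect_length(v, 19392L)
  expect_equal(v, flattenCycle(c1))
  z <- array(0, dim = dim(c1))
  expect_equal(assembleKinematicFeatures(list(c1, -c1, c1, -c1, z)),
               rep(0, 19392L))
  expect_error(assembleKinematicFeatures(
    list(c1, array(0, dim = c(50L, 64L, 3L)))), "mismatch")
})

test_that("flatten and unflatten are exact inverses", {
  set.seed(4)
  cyc <- array(rnorm(101 * 64 * 3), dim = c(101L, 64L, 3L))
  v <- flattenCycle(cyc)
  back <- unflattenFeatures(v, "kinematic")
  expect_equal(back, cyc, ignore_attr = TRUE)
  # layout check: marker-major blocks of 3 axes x 101 points
  expect_equal(v[1:101], cyc[, 1L, 1L])
  expect_equal(v[102:202], cyc[, 1L, 2L])
  expect_equal(v[(3 * 101 + 1):(3 * 101 + 101)], cyc[, 2L, 1L])
})

test_that("features are offset-invariant and scale inversely with height", {
  fx <- registeredFixture()
  trial <- fx$reg$trial
  kf1 <- kinematicFeatures(trial, height = 1.8)
  shifted <- methods::initialize(trial,
    positions = sweep(trialPositions(trial), 3L, c(0.3, -0.2, 1.1), "+"))
  kf2 <- kinematicFeatures(shifted, height = 1.8)
  expect_equal(kf2$features, kf1$features, tolerance = 1e-9)
  kf3 <- kinematicFeatures(trial, height = 0.9)
  expect_equal(kf3$features, kf1$features * 2, tolerance = 1e-9)
})
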
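# Synthetic sprint cohorts with known ground truth.
#
# Each subject accelerates along +x to a subject-specific peak speed,
# every marker follows a body-layout offset plus sinusoidal harmonics of
# the stride frequency, and known modes of variation perturb the
# harmonic content. Mode scores (plus a sex effect and Gaussian noise)
# determine each subject's peak velocity through a known linear model,
# so the downstream PCA + stepwise pipeline has a recoverable truth.
# Recorded coordinates carry linear lateral drift and a yaw-misaligned
# global frame, which registration must undo.

SYNTH_REF_HEIGHT <- 1.77  # m; anatomy offsets are defined at this height
SYNTH_ACCEL_TAU <- 1.7    # s; time constant of the acceleration phase

#' Construct a CohortSpec
#'
#' Defaults describe the study conditions the generator emulates: a
#' 40-subject cohort sprinting ~60 m to peak speeds near 8 m/s, three
#' kinematic modes of variation linearly linked to peak velocity, a
#' 0.5 m/s sex effect, 0.05 m/s residual velocity noise, lateral drift
#' and a yaw-misaligned recording frame.
#'
#' @param nSubjects number of subjects (>= 4).
#' @param nModesKinematic,nModesEmg injected modes per data set.
#' @param trueCoefficients data.frame(mode, weight): m/s per unit score
#'   for each velocity-linked kinematic mode.
#' @param sexEffect m/s added for male subjects (sex = 1).
#' @param noiseSdVelocity sd of the Gaussian velocity residual, m/s.
#' @param driftRate lateral positional drift, m/s.
#' @param frameYawDeg yaw misalignment of the recording frame, degrees.
#' @param strideRateHz strides per second.
#' @param velocityIntercept baseline female peak velocity, m/s.
#' @param modeScoreSd per-mode score sd (recycled).
#' @param seed master seed (integer).
#' @return a validated \linkS4class{CohortSpec}.
#' @export
cohortSpec <- function(nSubjects = 40L, nModesKinematic = 3L,
                       nModesEmg = 2L,
                       trueCoefficients = data.frame(
                         mode = seq_len(nModesKinematic),
                         weight = rep_len(c(1.6, -1.2, 2.0),
                                          nModesKinematic)),
                       sexEffect = 0.5, noiseSdVelocity = 0.05,
                       driftRate = 0.05, frameYawDeg = 15,
                       strideRateHz = 2, velocityIntercept = 7.7,
                       modeScoreSd = rep_len(c(0.25, 0.18, 0.12),
                                             nModesKinematic),
                       seed = 1L) {
  trueCoefficients <- as.data.frame(trueCoefficients)
  methods::new("CohortSpec",
    nSubjects = as.integer(nSubjects),
    nModesKinematic = as.integer(nModesKinematic),
    nModesEmg = as.integer(nModesEmg),
    trueCoefficients = trueCoefficients,
    sexEffect = sexEffect, noiseSdVelocity = noiseSdVelocity,
    driftRate = driftRate, frameYawDeg = frameYawDeg,
    strideRateHz = strideRateHz, velocityIntercept = velocityIntercept,
    modeScoreSd = as.numeric(modeScoreSd), seed = as.integer(seed))
}

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec:", object@nSubjects, "subjects,",
      object@nModesKinematic, "kinematic +", object@nModesEmg,
      "EMG modes, seed", object@seed, "\n")
  cat("  velocity model: ", object@velocityIntercept, " + ",
      paste(sprintf("%+.2f*z%d", object@trueCoefficients$weight,
                    object@trueCoefficients$mode), collapse = " "),
      sprintf(" %+.2f*sex + N(0, %.2f)", object@sexEffect,
              object@noiseSdVelocity), "\n", sep = "")
})

# --- deterministic anatomy and gait tables ----------------------------

# standing height (m at reference stature) of each marker, by name
.markerHeightTable <- function(labels) {
  rules <- list(
    c("HeadTop", 1.72), c("Head", 1.64), c("C7", 1.50), c("Neck", 1.54),
    c("T8", 1.32), c("T12", 1.20), c("L5", 1.10),
    c("Sternum", 1.38), c("Xiphoid", 1.28),
    c("Clavicle", 1.45), c("Scapula", 1.40), c("Shoulder", 1.47),
    c("Acromion", 1.49), c("UpperArm", 1.25), c("Elbow", 1.10),
    c("Forearm", 0.97), c("Wrist", 0.85), c("HandTip", 0.70),
    c("Hand", 0.77), c("ASIS", 1.00), c("PSIS", 1.02), c("Sacrum", 1.05),
    c("Thigh", 0.75), c("Knee", 0.50), c("Shank", 0.30),
    c("Ankle", 0.10), c("Heel", 0.05), c("ToeTip", 0.03), c("Toe", 0.05),
    c("Foot", 0.07))
  vapply(labels, function(lb) {
    for (r in rules) if (grepl(r[1], lb, fixed = TRUE))
      return(as.numeric(r[2]))
    1.0
  }, numeric(1L))
}

# offsets (m at reference stature): x anterior-posterior, y mediolateral
# (left positive), z vertical
.markerOffsets <- function(labels) {
  z <- .markerHeightTable(labels)
  side <- ifelse(grepl("^Right", labels), -1,
          ifelse(grepl("^Left", labels), 1, 0))
  arm <- grepl("Arm|Elbow|Forearm|Wrist|Hand", labels)
  yMag <- ifelse(arm, 0.24, ifelse(side != 0, 0.13, 0))
  y <- side * yMag +
    ifelse(labels %in% c("HeadLeft"), 0.08,
    ifelse(labels %in% c("HeadRight"), -0.08, 0))
  x <- ifelse(grepl("Front|Sternum|Xiphoid|ASIS", labels), 0.10,
       ifelse(grepl("Heel|PSIS|Scapula", labels), -0.08,
       ifelse(grepl("Toe", labels), 0.14, 0)))
  cbind(x = x, y = y, z = z)
}

# harmonic amplitude (m) and phase tables, 64 x 3 x 2 each; a fixed
# quasi-random pattern so every run shares the same "gait"
.gaitHarmonics <- function(labels) {
  n <- length(labels)
  limb <- grepl("Arm|Elbow|Forearm|Wrist|Hand|Thigh|Knee|Shank|Ankle|Heel|Toe|Foot",
                labels)
  axisBase <- c(x = 0.11, y = 0.06, z = 0.07)
  A <- array(0, dim = c(n, 3L, 2L))
  P <- array(0, dim = c(n, 3L, 2L))
  for (a in 1:3) {
    for (h in 1:2) {
      wob <- 0.5 + 0.5 * sin(seq_len(n) * 2.3 + a * 1.7 + h * 0.9)
      A[, a, h] <- axisBase[a] * ifelse(limb, 1, 0.25) * wob *
        if (h == 2L) 0.35 else 1
      P[, a, h] <- ((seq_len(n) * 1.3 + a * 2.1 + h * 0.7) %% (2 * pi))
    }
  }
  # the right/left ankle vertical trajectories anchor stride
  # segmentation: minima exactly at integer (resp. half-integer) phase
  for (side in c("RightAnkle", "LeftAnkle")) {
    i <- match(side, labels)
    if (is.na(i)) next
    A[i, 3L, ] <- c(0.06, 0.010)
    P[i, 3L, ] <- if (side == "RightAnkle") c(-pi / 2, -pi / 2)
                  else c(pi / 2, -pi / 2)
  }
  list(A = A, P = P)
}

# Kinematic mode waveforms: smooth periodic perturbations with disjoint
# marker support, zero on T8 / T12 / RightAnkle so speed, de-bias and
# segmentation are untouched. Returned as a features x modes matrix of
# unit-norm columns plus the per-mode support bookkeeping.
.kinematicModes <- function(labels, nModes) {
  if (nModes == 0L)
    return(list(matrix = matrix(0, KIN_FEATURE_LENGTH, 0L), support = list()))
  reserved <- c("T8", "T12", "RightAnkle")
  pool <- list(
    c("RightWristRad", "LeftWristRad"),
    c("RightKneeLat", "LeftKneeLat"),
    c("RightElbowLat", "LeftElbowLat"),
    c("RightShank", "LeftShank"),
    c("HeadTop", "HeadFront"),
    c("RightUpperArm", "LeftUpperArm"),
    c("RightThigh", "LeftThigh"),
    c("RightHeel", "LeftHeel"))
  if (nModes > length(pool))
    stop("at most ", length(pool), " kinematic modes are supported")
  s <- (0:100) / 100
  M <- matrix(0, KIN_FEATURE_LENGTH, nModes)
  support <- vector("list", nModes)
  for (k in seq_len(nModes)) {
    markers <- setdiff(pool[[k]], reserved)
    axis <- 1L + (k - 1L) %% 3L
    shape <- sin(2 * pi * (1L + (k - 1L) %% 3L) * s + k)
    shape <- shape - mean(shape)
    # periodic continuity: first and last normalized points coincide
    shape[101L] <- shape[1L]
    cols <- integer(0)
    for (m in markers) {
      mi <- match(m, labels)
      col <- (mi - 1L) * 3L + axis  # marker-axis index, axis fastest
      cols <- c(cols, col)
      sgn <- if (startsWith(m, "Left")) -1 else 1
      M[((col - 1L) * 101L + 1L):(col * 101L), k] <- sgn * shape
    }
    nrm <- sqrt(sum(M[, k]^2))
    M[, k] <- M[, k] / nrm
    support[[k]] <- list(cols = cols, markers = markers, axis = axis,
                         scale = 1 / nrm)
  }
  list(matrix = M, support = support)
}

# EMG burst table: per-channel burst center (stride-phase fraction),
# width and raw amplitude
.emgBurstTable <- function() {
  data.frame(
    channel = emgChannels(),
    center = c(0.15, 0.85, 0.90, 0.10, 0.12, 0.55, 0.80, 0.35, 0.45),
    width = 0.07,
    amplitude = c(0.55, 0.45, 0.40, 0.35, 0.50, 0.40, 0.35, 0.30, 0.30))
}

# per-subject deterministic RNG stream
.subjectSeed <- function(seed, subjectIndex) {
  as.integer((as.numeric(seed) * 48271 + subjectIndex * 1299721 + 17) %%
               2147483647)
}

# Draw one subject's covariates, mode scores and velocity.  The draw
# order is fixed so trials are bit-reproducible per (seed, subject).
.subjectParams <- function(subjectIndex, spec, seed = spec@seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(.subjectSeed(seed, subjectIndex))
  sex <- as.numeric(runif(1) < 0.675)            # cohort skews male
  age <- round(min(max(rnorm(1, 21.8, 3.2), 18), 35))
  height <- min(max(rnorm(1, 1.768, 0.084), 1.55), 2.00)
  kinScores <- if (spec@nModesKinematic > 0L)
    rnorm(spec@nModesKinematic, 0, spec@modeScoreSd) else numeric(0)
  emgScores <- if (spec@nModesEmg > 0L)
    rnorm(spec@nModesEmg, 0, 1) else numeric(0)
  vNoise <- rnorm(1, 0, spec@noiseSdVelocity)
  jitter <- matrix(1 + rnorm(64L * 3L, 0, 0.02), 64L, 3L)
  contrib <- 0
  if (nrow(spec@trueCoefficients))
    contrib <- sum(spec@trueCoefficients$weight *
                   kinScores[spec@trueCoefficients$mode])
  vmax <- spec@velocityIntercept + contrib + spec@sexEffect * sex + vNoise
  vmax <- max(vmax, 4)
  list(id = sprintf("S%02d", subjectIndex), sex = sex, age = age,
       height = height, kinScores = kinScores, emgScores = emgScores,
       vNoise = vNoise, jitter = jitter, vmax = vmax)
}

# body x-position under an exponential acceleration profile
.bodyX <- function(t, vmax, tau = SYNTH_ACCEL_TAU) {
  vmax * (t - tau * (1 - exp(-t / tau)))
}

#' Generate one subject's synthetic trials
#'
#' Builds the marker trial (60 Hz, 64 markers) and the EMG trial
#' (2000 Hz, 9 channels) for one subject of a cohort. The trial is long
#' enough for the trunk to travel past 62 m; recorded positions carry
#' the spec's lateral drift and yaw misalignment. Injected kinematic
#' modes are defined in the flattened feature layout and folded back
#' into the trajectories as periodic, height-scaled perturbations of the
#' stride cycle; EMG modes shift burst timing (odd modes) or scale burst
#' amplitude (even modes).
#'
#' @param subjectIndex 1-based subject number.
#' @param spec a \linkS4class{CohortSpec}.
#' @param seed seed override (defaults to the spec's seed). The same
#'   (subjectIndex, seed) always yields bit-identical trials.
#' @param what "both", "kinematic" or "emg".
#' @return list with \code{marker} (\linkS4class{MarkerTrial}),
#'   \code{emg} (\linkS4class{EmgTrial}) and \code{params} (the
#'   subject's ground-truth draws).
#' @export
generateTrial <- function(subjectIndex, spec, seed = spec@seed,
                          what = c("both", "kinematic", "emg")) {
  stopifnot(is(spec, "CohortSpec"))
  methods::validObject(spec)
  what <- match.arg(what)
  par <- .subjectParams(subjectIndex, spec, seed)
  labels <- markerLabels()

  duration <- 63 / par$vmax + SYNTH_ACCEL_TAU + 0.5
  nStrides <- duration * spec@strideRateHz
  if (nStrides < 7.5)
    stop(errorCondition(
      sprintf("trial too short for five strides: %.1f s at %.2f strides/s gives %.1f strides",
              duration, spec@strideRateHz, nStrides),
      class = c("sprintmodesShortTrial", "error", "condition")))

  marker <- NULL
  if (what != "emg") {
    rate <- 60
    nF <- as.integer(ceiling(duration * rate)) + 1L
    t <- (seq_len(nF) - 1L) / rate
    phi <- spec@strideRateHz * t
    hs <- par$height / SYNTH_REF_HEIGHT

    off <- .markerOffsets(labels) * hs
    gh <- .gaitHarmonics(labels)
    pos <- array(0, dim = c(nF, 64L, 3L))
    s1 <- sin(2 * pi * phi); c1 <- cos(2 * pi * phi)
    s2 <- sin(4 * pi * phi); c2 <- cos(4 * pi * phi)
    for (a in 1:3) {
      amp1 <- gh$A[, a, 1L] * par$jitter[, a] * hs
      amp2 <- gh$A[, a, 2L] * par$jitter[, a] * hs
      # sin(2*pi*h*phi + P) expanded so the time loop vectorizes
      pos[, , a] <-
        outer(s1, amp1 * cos(gh$P[, a, 1L])) +
        outer(c1, amp1 * sin(gh$P[, a, 1L])) +
        outer(s2, amp2 * cos(gh$P[, a, 2L])) +
        outer(c2, amp2 * sin(gh$P[, a, 2L])) +
        matrix(off[, a], nF, 64L, byrow = TRUE)
    }
    pos[, , 1L] <- pos[, , 1L] + .bodyX(t, par$vmax)

    # fold the feature-space modes back into the trajectories
    if (spec@nModesKinematic > 0L) {
      km <- .kinematicModes(labels, spec@nModesKinematic)
      sGrid <- (0:100) / 100
      phiWrap <- phi - floor(phi)
      for (k in seq_len(spec@nModesKinematic)) {
        sup <- km$support[[k]]
        for (j in seq_along(sup$cols)) {
          col <- sup$cols[j]
          mi <- (col - 1L) %/% 3L + 1L
          ax <- (col - 1L) %% 3L + 1L
          shape <- km$matrix[((col - 1L) * 101L + 1L):(col * 101L), k]
          wave <- approx(sGrid, shape, xout = phiWrap)$y
          pos[, mi, ax] <- pos[, mi, ax] +
            par$height * par$kinScores[k] * wave
        }
      }
    }

    # recording imperfections: lateral drift, then yaw misalignment
    pos[, , 2L] <- pos[, , 2L] + spec@driftRate * t
    if (spec@frameYawDeg != 0) {
      th <- spec@frameYawDeg * pi / 180
      xr <- pos[, , 1L] * cos(th) - pos[, , 2L] * sin(th)
      yr <- pos[, , 1L] * sin(th) + pos[, , 2L] * cos(th)
      pos[, , 1L] <- xr
      pos[, , 2L] <- yr
    }
    marker <- markerTrial(pos, labels, rate,
                          list(id = par$id, height = par$height,
                               sex = par$sex, age = par$age))
  }

  emg <- NULL
  if (what != "kinematic") {
    erate <- 2000
    nE <- as.integer(ceiling(duration * erate)) + 1L
    te <- (seq_len(nE) - 1L) / erate
    phiE <- spec@strideRateHz * te
    tab <- .emgBurstTable()
    sig <- matrix(0, nE, 9L)
    # EMG modes: odd modes shift the posterior-chain burst timing,
    # even modes scale the anterior-chain burst amplitude
    shiftCh <- c("BF", "GMAX", "LES", "LD")
    scaleCh <- c("EO", "VLO", "RF", "GAS")
    for (ch in 1:9) {
      shift <- 0; gain <- 1
      if (spec@nModesEmg >= 1L && tab$channel[ch] %in% shiftCh)
        shift <- 0.05 * sum(par$emgScores[seq(1L, spec@nModesEmg, by = 2L)])
      if (spec@nModesEmg >= 2L && tab$channel[ch] %in% scaleCh)
        gain <- exp(0.25 * sum(par$emgScores[seq(2L, spec@nModesEmg, by = 2L)]))
      d <- (phiE - tab$center[ch] - shift) %% 1
      d <- pmin(d, 1 - d)                      # wrapped phase distance
      env <- tab$amplitude[ch] * gain * exp(-d^2 / (2 * tab$width[ch]^2))
      sig[, ch] <- env
    }
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(.subjectSeed(seed, subjectIndex) %% 2000000011L + 7L)
    sig <- sig + matrix(rnorm(nE * 9L, 0, 0.02), nE, 9L)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    colnames(sig) <- emgChannels()
    emg <- emgTrial(sig, rate = erate)
  }

  list(marker = marker, emg = emg, params = par)
}

#' Generate a full synthetic cohort
#'
#' Calls \code{\link{generateTrial}} for every subject and assembles the
#' covariates table and the \code{truth} object: the injected unit-norm
#' mode waveforms (feature space), the subjects' mode scores, the true
#' velocity model and each subject's true peak velocity.
#'
#' @param spec a \linkS4class{CohortSpec}.
#' @param what "both", "kinematic" or "emg" (which trials to build).
#' @return list with \code{trials} (per-subject lists), \code{covariates}
#'   (data.frame id, height, sex, age, peakVelocityTrue) and
#'   \code{truth} (modeWaveforms, modeScores, emgModeScores,
#'   trueCoefficients, sexEffect, intercept, featureOffsets).
#' @export
generateCohort <- function(spec, what = c("both", "kinematic", "emg")) {
  stopifnot(is(spec, "CohortSpec"))
  methods::validObject(spec)
  what <- match.arg(what)
  n <- spec@nSubjects
  trials <- vector("list", n)
  pars <- vector("list", n)
  for (i in seq_len(n)) {
    trials[[i]] <- generateTrial(i, spec, what = what)
    pars[[i]] <- trials[[i]]$params
  }
  covariates <- data.frame(
    id = vapply(pars, `[[`, "", "id"),
    height = vapply(pars, `[[`, 0, "height"),
    sex = vapply(pars, `[[`, 0, "sex"),
    age = vapply(pars, `[[`, 0, "age"),
    peakVelocityTrue = vapply(pars, `[[`, 0, "vmax"))
  km <- .kinematicModes(markerLabels(), spec@nModesKinematic)
  modeScores <- if (spec@nModesKinematic > 0L)
    t(vapply(pars, `[[`, numeric(spec@nModesKinematic), "kinScores"))
  else matrix(0, n, 0L)
  emgScores <- if (spec@nModesEmg > 0L)
    t(vapply(pars, `[[`, numeric(spec@nModesEmg), "emgScores"))
  else matrix(0, n, 0L)
  if (spec@nModesKinematic == 1L) modeScores <- matrix(modeScores, ncol = 1L)
  if (spec@nModesEmg == 1L) emgScores <- matrix(emgScores, ncol = 1L)
  truth <- list(
    modeWaveforms = km$matrix,
    modeScores = modeScores,
    emgModeScores = emgScores,
    trueCoefficients = spec@trueCoefficients,
    sexEffect = spec@sexEffect,
    intercept = spec@velocityIntercept,
    featureOffsets = modeScores %*% t(km$matrix))
  list(trials = trials, covariates = covariates, truth = truth)
}
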
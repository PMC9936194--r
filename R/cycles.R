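# Stride-cycle extraction: speed profile and peak, right-ankle-minima
# stride segmentation, selection of five cycles about peak velocity,
# time normalization to 101 points, T12 de-bias, height scaling, and
# assembly of the flattened kinematic feature vector.

N_KIN_POINTS <- 101L
KIN_FEATURE_LENGTH <- 64L * 3L * 101L  # 19392

# Central-difference derivative at the sampling rate (one-sided at the
# ends), matching numerical gradient conventions.
.gradient <- function(x, dt) {
  n <- length(x)
  g <- numeric(n)
  if (n < 2L) return(g)
  g[1L] <- (x[2L] - x[1L]) / dt
  g[n] <- (x[n] - x[n - 1L]) / dt
  if (n > 2L)
    g[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / (2 * dt)
  g
}

#' Per-frame speed profile of the trunk marker
#'
#' Differentiates the T8 trajectory at the trial rate using central
#' differences. The default \code{mode = "vector"} takes the norm of the
#' position derivative, which is origin- and direction-independent;
#' \code{mode = "norm-derivative"} takes the derivative of the position
#' norm instead (the distance-from-origin reading), which after
#' registration nearly coincides with the vector mode for forward
#' sprinting.
#'
#' @param trial registered \linkS4class{MarkerTrial} (>= 3 frames).
#' @param mode speed definition, see Details.
#' @param marker which marker carries the body's speed (default T8).
#' @return list with \code{speed} (m/s per frame), \code{peakSpeed},
#'   \code{peakFrame} (first frame attaining the maximum).
#' @export
speedProfile <- function(trial, mode = c("vector", "norm-derivative"),
                         marker = "T8") {
  stopifnot(is(trial, "MarkerTrial"))
  mode <- match.arg(mode)
  p <- .markerXYZ(trial, marker)
  if (nrow(p) < 3L) stop("at least 3 frames are required for a speed profile")
  dt <- 1 / trial@rate
  if (mode == "vector") {
    v <- vapply(1:3, function(a) .gradient(p[, a], dt), numeric(nrow(p)))
    speed <- sqrt(rowSums(v^2))
  } else {
    speed <- .gradient(sqrt(rowSums(p^2)), dt)
  }
  peakFrame <- which.max(speed)  # first occurrence on ties
  list(speed = speed, peakSpeed = speed[peakFrame], peakFrame = peakFrame)
}

# Dual-pass low-pass smoothing used before trough detection (4 Hz keeps
# stride-frequency content while suppressing marker jitter).
.smoothLowpass <- function(x, rate, cutoffHz = 4) {
  if (cutoffHz >= rate / 2) return(x)
  bf <- signal::butter(2, cutoffHz / (rate / 2), type = "low")
  .filtfilt(bf$b, bf$a, x)
}

#' Detect stride events as right-ankle height minima
#'
#' Smooths the right-ankle z trajectory (dual-pass 2nd-order low-pass,
#' 4 Hz) and returns the frames of its local minima, enforcing a minimum
#' separation of 0.3 times the dominant inter-trough interval estimated
#' from the autocorrelation of the detrended signal. A stride is the
#' interval between consecutive events (one full gait cycle of the
#' right side). Events are invariant to constant height offsets.
#'
#' @param trial registered \linkS4class{MarkerTrial}.
#' @param smoothHz smoothing cutoff in Hz.
#' @param minEvents minimum acceptable number of minima (6 are needed
#'   for five stride windows).
#' @return strictly increasing integer frame indices.
#' @export
detectStrideMinima <- function(trial, smoothHz = 4, minEvents = 6L) {
  stopifnot(is(trial, "MarkerTrial"))
  z <- .markerXYZ(trial, "RightAnkle")[, 3]
  n <- length(z)
  if (n < 5L) stop("too few strides: trial has fewer than 5 frames")
  zs <- .smoothLowpass(z, trial@rate, smoothHz)

  # dominant period from the first autocorrelation peak of the
  # detrended height signal
  zc <- zs - mean(zs)
  maxLag <- min(n - 2L, as.integer(3 * trial@rate))
  ac <- stats::acf(zc, lag.max = maxLag, plot = FALSE)$acf[-1L]
  pk <- which(diff(sign(diff(ac))) < 0) + 1L
  pk <- pk[ac[pk] > 0]
  period <- if (length(pk)) pk[1L] else as.integer(trial@rate / 2)
  minSep <- max(2L, as.integer(floor(0.3 * period)))

  # strict local minima (ties broken to the earliest frame)
  interior <- 2:(n - 1L)
  cand <- interior[zs[interior] < zs[interior - 1L] &
                   zs[interior] <= zs[interior + 1L]]
  if (length(cand)) {
    ord <- order(zs[cand], cand)  # deepest first, earliest on ties
    keep <- logical(length(cand))
    taken <- integer(0)
    for (i in ord) {
      if (!length(taken) || all(abs(cand[i] - taken) >= minSep)) {
        keep[i] <- TRUE
        taken <- c(taken, cand[i])
      }
    }
    cand <- sort(cand[keep])
  }
  if (length(cand) < minEvents)
    stop("too few strides: found ", length(cand), " ankle-height minima, need ",
         minEvents)
  cand
}

#' Select five stride windows about the peak-velocity frame
#'
#' Stride windows are the intervals between consecutive events. The
#' window containing \code{peakFrame} is placed centrally (window 3 of
#' 5); when the peak falls within the first or last two windows the
#' five-window block shifts inward to stay in range. With exactly six
#' events there is a single possible block.
#'
#' @param events increasing stride-event frames (>= 6).
#' @param peakFrame frame index of peak speed.
#' @return integer matrix with 5 rows and columns \code{start},
#'   \code{end}: frame intervals \code{[start, end]} spanning one
#'   stride each (shared endpoints).
#' @export
selectCyclesAboutPeak <- function(events, peakFrame) {
  nw <- length(events) - 1L
  if (nw < 5L)
    stop("need at least 6 stride events for five windows, got ", length(events))
  # window containing the peak (clamped to range)
  w <- findInterval(peakFrame, events, rightmost.closed = TRUE)
  w <- min(max(w, 1L), nw)
  first <- min(max(w - 2L, 1L), nw - 4L)
  idx <- first:(first + 4L)
  cbind(start = events[idx], end = events[idx + 1L])
}

#' Time-normalize one stride cycle
#'
#' Resamples every marker-axis series within \code{[start, end]}
#' (inclusive) onto \code{nPoints} equally spaced time points using a
#' cubic spline, subtracts the T12 position (x, y, z) from all markers
#' at every normalized point so forward progression is removed, and
#' divides by the subject height so features are dimensionless.
#'
#' @param trial registered \linkS4class{MarkerTrial}.
#' @param window length-2 integer (start, end frames) with
#'   \code{end - start >= 3}.
#' @param nPoints number of normalized time points (default 101).
#' @param height subject height in meters; defaults to the trial's
#'   subject metadata.
#' @return nPoints x 64 x 3 array of de-biased, height-scaled positions.
#' @export
normalizeCycle <- function(trial, window, nPoints = N_KIN_POINTS,
                           height = NULL) {
  stopifnot(is(trial, "MarkerTrial"))
  if (is.null(height)) height <- trial@subject$height
  if (is.null(height) || is.na(height) || height <= 0)
    stop("subject height must be a positive number of meters")
  s <- as.integer(window[1L]); e <- as.integer(window[2L])
  if (e - s < 3L) stop("cycle window must span at least 4 frames")
  frames <- s:e
  tOut <- seq(s, e, length.out = nPoints)
  d <- dim(trial@positions)
  flat <- matrix(trial@positions[frames, , ], nrow = length(frames))
  res <- apply(flat, 2L, function(y) spline(frames, y, xout = tOut)$y)
  cyc <- array(res, dim = c(nPoints, d[2], 3L))
  t12 <- cyc[, .markerIndex(trial, "T12"), , drop = FALSE]
  cyc <- cyc - t12[, rep(1L, d[2]), , drop = FALSE]
  cyc / height
}

#' Flatten a cycle array into the feature layout
#'
#' Marker-major, then axis (x, y, z), then time: feature index
#' \code{((m-1)*3 + (a-1)) * nPoints + t}. The inverse is
#' \code{\link{unflattenFeatures}}.
#'
#' @param cycle nPoints x markers x 3 array.
#' @return numeric vector of length markers * 3 * nPoints.
#' @export
flattenCycle <- function(cycle) {
  # reorder to time-within-axis-within-marker
  as.vector(aperm(cycle, c(1L, 3L, 2L)))
}

#' Assemble the per-subject kinematic feature vector
#'
#' Ensemble-averages five normalized cycles pointwise and flattens the
#' mean cycle into the 1 x 19392 layout (64 markers x 3 axes x 101 time
#' points).
#'
#' @param cycles list of five nPoints x 64 x 3 arrays of identical shape.
#' @return numeric feature vector of length 19392.
#' @export
assembleKinematicFeatures <- function(cycles) {
  if (!length(cycles)) stop("no cycles supplied")
  d <- dim(cycles[[1L]])
  for (c in cycles)
    if (!identical(dim(c), d)) stop("cycle shape mismatch")
  mean_cycle <- Reduce("+", cycles) / length(cycles)
  v <- flattenCycle(mean_cycle)
  if (d[2] == 64L && d[1] == N_KIN_POINTS)
    stopifnot(length(v) == KIN_FEATURE_LENGTH)
  v
}

#' Full kinematic feature extraction for one registered trial
#'
#' Speed profile, stride events, five cycles about peak, time
#' normalization and feature assembly in one call.
#'
#' @param trial registered \linkS4class{MarkerTrial}.
#' @param height subject height in meters (defaults to trial metadata).
#' @return list with \code{features} (length 19392), \code{peakSpeed},
#'   \code{peakFrame}, \code{events}, \code{windows}.
#' @export
kinematicFeatures <- function(trial, height = NULL) {
  sp <- speedProfile(trial)
  events <- detectStrideMinima(trial)
  windows <- selectCyclesAboutPeak(events, sp$peakFrame)
  cycles <- lapply(seq_len(nrow(windows)), function(i)
    normalizeCycle(trial, windows[i, ], height = height))
  list(features = assembleKinematicFeatures(cycles),
       peakSpeed = sp$peakSpeed, peakFrame = sp$peakFrame,
       events = events, windows = windows)
}
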
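# Surface-EMG processing: full-wave rectification, zero-phase dual-pass
# Butterworth linear envelope, residual-analysis cutoff selection
# (Winter's construction), dynamic peak amplitude normalization, and
# assembly of the flattened 9 x 2000 EMG feature vector.

N_EMG_POINTS <- 2000L
EMG_FEATURE_LENGTH <- 9L * 2000L  # 18000

# Single IIR pass with steady-state initial conditions: pre-history is
# treated as an infinite run of x[1], so a constant input passes through
# exactly (DC gain to machine precision).
.iirPass <- function(b, a, x) {
  b <- b / a[1L]; a <- a / a[1L]
  nb <- length(b); na <- length(a)
  u <- stats::filter(c(rep(x[1L], nb - 1L), x), b,
                     method = "convolution", sides = 1)
  u <- as.numeric(u)[nb:(length(x) + nb - 1L)]
  if (na == 1L) return(u)
  g <- sum(b) / sum(a)
  y <- stats::filter(u, -a[-1L], method = "recursive",
                     init = rep(x[1L] * g, na - 1L))
  as.numeric(y)
}

# Zero-phase forward-backward filtering with odd-reflection padding
# (the filtfilt construction). Effective order is twice the design
# order and the magnitude response is |H|^2.
.filtfilt <- function(b, a, x) {
  n <- length(x)
  np <- 3L * (max(length(a), length(b)) - 1L)
  np <- min(np, n - 1L)
  if (np > 0L) {
    front <- 2 * x[1L] - x[seq(np + 1L, 2L)]
    back <- 2 * x[n] - x[seq(n - 1L, n - np)]
    xp <- c(front, x, back)
  } else xp <- x
  y <- .iirPass(b, a, xp)
  y <- rev(.iirPass(b, a, rev(y)))
  if (np > 0L) y[(np + 1L):(np + n)] else y
}

.butterLowpass <- function(cutoffHz, rate) {
  if (cutoffHz >= rate / 2)
    stop("cutoff (", cutoffHz, " Hz) must be below the Nyquist frequency (",
         rate / 2, " Hz)")
  signal::butter(2, cutoffHz / (rate / 2), type = "low")
}

#' Zero-phase dual-pass Butterworth low-pass filter
#'
#' Filters forward and backward with a 2nd-order Butterworth low-pass
#' (odd-reflection padding, steady-state initial conditions), giving an
#' effective 4th-order zero-phase response with magnitude |H|^2: unity
#' DC gain and about 0.5 at the cutoff frequency.
#'
#' @param x numeric vector.
#' @param rate sampling rate in Hz.
#' @param cutoffHz cutoff frequency in Hz (below Nyquist).
#' @return the filtered vector.
#' @export
dualPassFilter <- function(x, rate, cutoffHz) {
  bf <- .butterLowpass(cutoffHz, rate)
  .filtfilt(bf$b, bf$a, x)
}

#' Compute the linear envelope of an EMG trial
#'
#' Full-wave rectifies each channel and applies a dual-pass (forward and
#' backward) 2nd-order Butterworth low-pass at \code{cutoffHz}. The dual
#' pass doubles the effective order and cancels phase lag, so burst
#' timing is preserved; slight filter undershoot below zero is clipped.
#' No cutoff-frequency correction is applied: the attenuation at
#' \code{cutoffHz} is the square of the single-pass response
#' (about 0.5).
#'
#' @param emg an \linkS4class{EmgTrial}.
#' @param cutoffHz low-pass cutoff in Hz (default 250; see
#'   \code{\link{residualAnalysis}} to derive one from the data).
#' @return an \linkS4class{EmgTrial} holding the nonnegative envelope.
#' @export
linearEnvelope <- function(emg, cutoffHz = 250) {
  stopifnot(is(emg, "EmgTrial"))
  bf <- .butterLowpass(cutoffHz, emg@rate)
  env <- apply(abs(emg@signal), 2L, function(x) .filtfilt(bf$b, bf$a, x))
  env[env < 0] <- 0
  colnames(env) <- colnames(emg@signal)
  methods::initialize(emg, signal = env)
}

#' Residual analysis for filter cutoff selection
#'
#' For each candidate cutoff, computes the per-channel RMS difference
#' between the dual-pass-filtered and the rectified raw signal. The
#' high-frequency end of the residual curve is noise-dominated and
#' nearly linear in cutoff; a straight line fitted through that tail is
#' extrapolated to zero frequency, and the chosen cutoff is where the
#' residual curve meets the extrapolated intercept (Winter's
#' construction) --- the point at which further smoothing starts
#' removing signal rather than noise. An infinite cutoff means no
#' filtering (residual 0).
#'
#' @param emg a raw \linkS4class{EmgTrial}.
#' @param cutoffs increasing candidate cutoffs in Hz (at least 4, so
#'   that a 3-point linear tail plus a lower candidate exist); values
#'   at or above Nyquist are treated as unfiltered.
#' @param tailFraction fraction of the highest cutoffs used for the
#'   linear tail fit (at least 3 points).
#' @return list with \code{cutoff} (chosen Hz per channel),
#'   \code{residuals} (cutoffs x channels RMS matrix),
#'   \code{intercept} (per-channel zero-frequency intercept).
#' @export
residualAnalysis <- function(emg, cutoffs, tailFraction = 0.3) {
  stopifnot(is(emg, "EmgTrial"))
  cutoffs <- sort(cutoffs)
  k <- length(cutoffs)
  if (k < 4L)
    stop("residual curve has no linear tail: supply at least 4 cutoffs ",
         "(3 high-frequency points plus a lower candidate)")
  rect <- abs(emg@signal)
  res <- matrix(0, k, ncol(rect),
                dimnames = list(NULL, colnames(rect)))
  for (i in seq_len(k)) {
    if (is.finite(cutoffs[i]) && cutoffs[i] < emg@rate / 2) {
      bf <- .butterLowpass(cutoffs[i], emg@rate)
      filt <- apply(rect, 2L, function(x) .filtfilt(bf$b, bf$a, x))
      res[i, ] <- sqrt(colMeans((filt - rect)^2))
    }  # else: unfiltered, residual stays 0
  }
  finite <- which(is.finite(cutoffs))
  if (length(finite) < 3L)
    stop("residual curve has no linear tail: at least 3 finite ",
         "high-frequency cutoffs are required")
  nTail <- max(3L, ceiling(tailFraction * length(finite)))
  tailIdx <- finite[seq.int(length(finite) - nTail + 1L, length(finite))]
  chosen <- numeric(ncol(rect))
  intercept <- numeric(ncol(rect))
  for (ch in seq_len(ncol(rect))) {
    fitCoef <- coef(lm(res[tailIdx, ch] ~ cutoffs[tailIdx]))
    a0 <- unname(fitCoef[1L])
    intercept[ch] <- a0
    # a residual floor of 0.1% of the signal RMS: below it the filter
    # removes nothing appreciable and the signal counts as noiseless,
    # in which case the lowest candidate is the answer
    floorTol <- 1e-3 * max(sqrt(mean(rect[, ch]^2)), 1e-30)
    if (a0 <= floorTol) {
      hit <- which(res[, ch] <= floorTol)
      chosen[ch] <- if (length(hit)) cutoffs[hit[1L]] else cutoffs[1L]
    } else {
      hit <- which(res[, ch] <= a0)
      chosen[ch] <- if (length(hit)) cutoffs[hit[1L]] else
        cutoffs[which.min(abs(res[, ch] - a0))]
    }
  }
  names(chosen) <- colnames(rect)
  list(cutoff = chosen, residuals = res, intercept = intercept)
}

# Strict local maxima with a minimum separation (larger peaks win;
# earliest frame wins ties).
.findPeaks <- function(x, minSep) {
  n <- length(x)
  if (n < 3L) return(integer())
  interior <- 2:(n - 1L)
  cand <- interior[x[interior] > x[interior - 1L] &
                   x[interior] >= x[interior + 1L]]
  if (!length(cand)) return(integer())
  ord <- order(-x[cand], cand)
  taken <- integer(0)
  for (i in ord) {
    if (!length(taken) || all(abs(cand[i] - taken) >= minSep))
      taken <- c(taken, cand[i])
  }
  sort(taken)
}

#' Amplitude-normalize an EMG envelope to its dynamic peak reference
#'
#' Divides each channel by the mean of its three highest local peaks
#' within \code{[1, windowEndFrame]} --- in the sprint pipeline, the
#' window covering the first 20 m of travel, so the reference is
#' obtained under the same dynamic conditions as the signal itself.
#' Peaks are strict local maxima separated by at least
#' \code{minPeakSeparation} seconds.
#'
#' @param emg an envelope \linkS4class{EmgTrial}.
#' @param windowEndFrame last EMG frame of the normalization window.
#' @param minPeakSeparation minimum peak spacing in seconds.
#' @return a normalized \linkS4class{EmgTrial} (dimensionless).
#' @export
amplitudeNormalize <- function(emg, windowEndFrame,
                               minPeakSeparation = 0.05) {
  stopifnot(is(emg, "EmgTrial"))
  windowEndFrame <- min(as.integer(windowEndFrame), nrow(emg@signal))
  minSep <- max(1L, as.integer(round(minPeakSeparation * emg@rate)))
  sig <- emg@signal
  for (ch in seq_len(ncol(sig))) {
    w <- sig[seq_len(windowEndFrame), ch]
    pk <- .findPeaks(w, minSep)
    if (length(pk) < 3L)
      stop("channel ", colnames(sig)[ch], " has ", length(pk),
           " peaks in the normalization window; at least 3 are required")
    top3 <- sort(w[pk], decreasing = TRUE)[1:3]
    sig[, ch] <- sig[, ch] / mean(top3)
  }
  methods::initialize(emg, signal = sig, normalized = TRUE)
}

#' Map kinematic frame indices onto the EMG timeline
#'
#' Assumes synchronized recording starts and exact nominal rates, so
#' frame k of the kinematic record corresponds to EMG frame
#' \code{round((k - 1) * emgRate / kinRate) + 1}.
#'
#' @param frames kinematic frame indices.
#' @param kinRate kinematic rate in Hz.
#' @param emgRate EMG rate in Hz.
#' @return integer EMG frame indices.
#' @export
mapFramesToEmg <- function(frames, kinRate = 60, emgRate = 2000) {
  as.integer(round((frames - 1) * emgRate / kinRate)) + 1L
}

#' Assemble the per-subject EMG feature vector
#'
#' Resamples each channel within each of the five stride windows
#' (already mapped to EMG frames) onto \code{nPoints} points with a
#' cubic spline, ensemble-averages the five cycles, and flattens
#' channel-major then time into a 1 x 18000 vector (9 channels x 2000
#' points).
#'
#' @param emg a normalized envelope \linkS4class{EmgTrial}.
#' @param windows 5 x 2 matrix of EMG-frame (start, end) intervals.
#' @param nPoints normalized points per cycle (default 2000).
#' @return numeric feature vector of length \code{9 * nPoints}.
#' @export
assembleEmgFeatures <- function(emg, windows, nPoints = N_EMG_POINTS) {
  stopifnot(is(emg, "EmgTrial"))
  n <- nrow(emg@signal)
  if (any(windows < 1L) || any(windows > n))
    stop("cycle window falls outside the EMG recording (frames 1..", n, ")")
  acc <- matrix(0, nPoints, ncol(emg@signal))
  for (i in seq_len(nrow(windows))) {
    frames <- windows[i, 1L]:windows[i, 2L]
    tOut <- seq(windows[i, 1L], windows[i, 2L], length.out = nPoints)
    cyc <- apply(emg@signal[frames, , drop = FALSE], 2L,
                 function(y) spline(frames, y, xout = tOut)$y)
    acc <- acc + cyc
  }
  acc <- acc / nrow(windows)
  as.vector(acc)  # time fastest within each channel block
}

#' Full EMG feature extraction for one trial
#'
#' Linear envelope, dynamic peak normalization over the first
#' \code{normDistance} meters of travel (taken from the registered
#' kinematic trial), mapping of the five kinematic stride windows onto
#' the EMG timeline, and feature assembly.
#'
#' @param emg raw \linkS4class{EmgTrial}.
#' @param kinTrial the registered \linkS4class{MarkerTrial} recorded
#'   simultaneously.
#' @param windows 5 x 2 kinematic-frame stride windows.
#' @param cutoffHz envelope cutoff in Hz.
#' @param normDistance travel distance defining the normalization
#'   window, meters.
#' @return list with \code{features} (length 18000), \code{envelope}
#'   (the normalized EmgTrial), \code{emgWindows}.
#' @export
emgFeatures <- function(emg, kinTrial, windows, cutoffHz = 250,
                        normDistance = 20) {
  env <- linearEnvelope(emg, cutoffHz)
  t8x <- .markerXYZ(kinTrial, "T8")[, 1]
  travel <- t8x - t8x[1L]
  hit <- which(travel >= normDistance)
  if (!length(hit))
    stop("kinematic trial never reaches ", normDistance,
         " m; cannot place the normalization window")
  endEmg <- mapFramesToEmg(hit[1L], kinTrial@rate, emg@rate)
  env <- amplitudeNormalize(env, endEmg)
  emgWindows <- cbind(
    start = mapFramesToEmg(windows[, 1L], kinTrial@rate, emg@rate),
    end   = mapFramesToEmg(windows[, 2L], kinTrial@rate, emg@rate))
  emgWindows[emgWindows > nrow(env@signal)] <- nrow(env@signal)
  list(features = assembleEmgFeatures(env, emgWindows),
       envelope = env, emgWindows = emgWindows)
}
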
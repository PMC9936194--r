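# Constructors, accessors and show methods for the trial containers.

.pkgCache <- new.env(parent = emptyenv())

#' Canonical marker and EMG channel manifests
#'
#' The 64-marker point-cloud label set used throughout the package, and
#' the fixed 9-channel EMG order. The marker manifest is shipped as
#' \code{extdata/marker_labels.txt}; vendor exports with different names
#' can be mapped onto it via the \code{labelMap} argument of
#' \code{\link{readMarkerTrial}}. The set must contain \code{T8},
#' \code{T12} and \code{RightAnkle}, which anchor the speed profile, the
#' de-bias step and stride segmentation respectively.
#'
#' @return character vector of 64 marker names / 9 channel names.
#' @export
markerLabels <- function() {
  if (is.null(.pkgCache$labels)) {
    path <- system.file("extdata", "marker_labels.txt", package = "sprintmodes")
    .pkgCache$labels <- readLines(path)
  }
  .pkgCache$labels
}

#' @rdname markerLabels
#' @export
emgChannels <- function() {
  c("GAS", "BF", "GMAX", "GMED", "VLO", "RF", "LES", "LD", "EO")
}

#' Construct a MarkerTrial
#'
#' @param positions frames x markers x 3 numeric array, meters.
#' @param labels marker names; defaults to the canonical 64-label set.
#' @param rate sampling rate in Hz.
#' @param subject named list with \code{id}, \code{height} (m),
#'   \code{sex} (0/1), \code{age} (years); missing elements are filled
#'   with NA.
#' @return a validated \linkS4class{MarkerTrial}.
#' @export
markerTrial <- function(positions, labels = markerLabels(), rate = 60,
                        subject = list()) {
  def <- list(id = NA_character_, height = NA_real_, sex = NA_real_,
              age = NA_real_)
  subject <- utils::modifyList(def, subject)
  dimnames(positions) <- list(NULL, labels, c("x", "y", "z"))
  methods::new("MarkerTrial", positions = positions, labels = labels,
               rate = rate, subject = subject)
}

#' Construct an EmgTrial
#'
#' @param signal frames x 9 numeric matrix; columns may arrive in any
#'   order if named, and are reordered to the canonical channel order.
#' @param rate sampling rate in Hz.
#' @param normalized whether amplitudes are already peak-normalized.
#' @return a validated \linkS4class{EmgTrial}.
#' @export
emgTrial <- function(signal, rate = 2000, normalized = FALSE) {
  signal <- as.matrix(signal)
  if (!is.null(colnames(signal))) {
    miss <- setdiff(emgChannels(), colnames(signal))
    if (length(miss))
      stop("EMG signal is missing channels: ", paste(miss, collapse = ", "))
    signal <- signal[, emgChannels(), drop = FALSE]
  } else {
    if (ncol(signal) != 9L)
      stop("unnamed EMG signal must have exactly 9 columns")
    colnames(signal) <- emgChannels()
  }
  methods::new("EmgTrial", signal = signal, rate = rate,
               normalized = normalized)
}

#' @rdname MarkerTrial-class
#' @export
setMethod("trialPositions", "MarkerTrial", function(object) object@positions)

#' @rdname MarkerTrial-class
#' @export
setMethod("trialRate", "MarkerTrial", function(object) object@rate)

#' @rdname EmgTrial-class
#' @export
setMethod("trialRate", "EmgTrial", function(object) object@rate)

#' @rdname MarkerTrial-class
#' @export
setMethod("trialSubject", "MarkerTrial", function(object) object@subject)

#' @rdname MarkerTrial-class
#' @export
setMethod("trialLabels", "MarkerTrial", function(object) object@labels)

#' @rdname EmgTrial-class
#' @export
setMethod("emgSignal", "EmgTrial", function(object) object@signal)

#' @rdname EmgTrial-class
#' @export
setMethod("isNormalized", "EmgTrial", function(object) object@normalized)

setMethod("show", "MarkerTrial", function(object) {
  d <- dim(object@positions)
  cat("MarkerTrial:", d[1], "frames x", d[2], "markers @", object@rate, "Hz\n")
  cat("  duration:", sprintf("%.2f s", d[1] / object@rate), "\n")
  s <- object@subject
  cat("  subject:", s$id, "| height", s$height, "m | sex", s$sex,
      "| age", s$age, "\n")
})

setMethod("show", "EmgTrial", function(object) {
  d <- dim(object@signal)
  cat("EmgTrial:", d[1], "frames x", d[2], "channels @", object@rate, "Hz",
      if (object@normalized) "(normalized)" else "(raw)", "\n")
})

# Marker index helpers used across the pipeline; error names the label
# so a bad vendor export fails loudly.
.markerIndex <- function(trial, label) {
  i <- match(label, trial@labels)
  if (is.na(i)) stop("marker '", label, "' not present in trial labels")
  i
}

.markerXYZ <- function(trial, label) {
  trial@positions[, .markerIndex(trial, label), , drop = TRUE]
}
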
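# Reading and writing trials in the pipeline's exchange formats:
# C3D for marker point clouds, delimited text for EMG, JSON for subject
# metadata.

# Linear interpolation of NA runs; runs longer than maxGapFrames, or
# NAs touching either end, are an error.
.fillGaps <- function(x, maxGapFrames, what) {
  if (!anyNA(x)) return(x)
  isna <- is.na(x)
  r <- rle(isna)
  gaps <- which(r$values)
  if (any(r$lengths[gaps] > maxGapFrames))
    stop("gap of ", max(r$lengths[gaps]), " frames in ", what,
         " exceeds the interpolatable maximum of ", maxGapFrames, " frames")
  if (isna[1L] || isna[length(x)])
    stop("missing data at the start or end of ", what, " cannot be interpolated")
  idx <- which(!isna)
  approx(idx, x[idx], xout = seq_along(x))$y
}

#' Read a marker trial from a C3D file
#'
#' Loads 3D point data (converted to meters per \code{POINT:UNITS}),
#' checks that all 64 canonical markers are present (after applying an
#' optional label map), reorders markers to the canonical order and
#' linearly interpolates dropout gaps of at most \code{maxGap} seconds.
#' Longer gaps are an error: the downstream analysis assumes complete
#' trajectories.
#'
#' @param path C3D file path.
#' @param subject named list of subject metadata (id, height in meters,
#'   sex with 0 = female / 1 = male, age in years).
#' @param labelMap optional named character vector mapping file labels
#'   to canonical labels (\code{c(fileLabel = "CanonicalLabel")}).
#' @param maxGap longest interpolatable dropout, seconds.
#' @return a \linkS4class{MarkerTrial}.
#' @export
readMarkerTrial <- function(path, subject = list(), labelMap = NULL,
                            maxGap = 0.25) {
  d <- readC3D(path)
  labels <- d$labels
  if (!is.null(labelMap)) {
    hit <- match(labels, names(labelMap))
    labels[!is.na(hit)] <- labelMap[hit[!is.na(hit)]]
  }
  canonical <- markerLabels()
  miss <- setdiff(canonical, labels)
  if (length(miss))
    stop("C3D file is missing canonical markers: ",
         paste(miss, collapse = ", "))
  ord <- match(canonical, labels)
  pos <- d$positions[, ord, , drop = FALSE]
  maxGapFrames <- max(1L, floor(maxGap * d$rate))
  if (anyNA(pos)) {
    for (m in seq_len(dim(pos)[2])) {
      for (a in 1:3) {
        pos[, m, a] <- .fillGaps(pos[, m, a], maxGapFrames,
                                 sprintf("marker %s axis %d", canonical[m], a))
      }
    }
  }
  markerTrial(pos, canonical, d$rate, subject)
}

#' Write a marker trial to a C3D file
#'
#' @param trial a \linkS4class{MarkerTrial}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeMarkerTrial <- function(trial, path) {
  stopifnot(is(trial, "MarkerTrial"))
  if (dim(trial@positions)[1] < 1L)
    stop("cannot write a trial with no frames")
  writeC3D(path, trial@positions, trial@labels, trial@rate)
}

#' Read an EMG trial from delimited text
#'
#' Expects a comma-delimited file with one header row naming the nine
#' canonical channels (in any order); an optional leading \code{time}
#' column (seconds from start) is used to infer the rate when present.
#' Columns are reordered to the canonical channel order.
#'
#' @param path CSV path.
#' @param rate sampling rate in Hz; overridden by a \code{time} column.
#' @return an \linkS4class{EmgTrial}.
#' @export
readEmgTrial <- function(path, rate = 2000) {
  df <- read.csv(path, check.names = FALSE)
  if ("time" %in% colnames(df)) {
    tm <- df$time
    df$time <- NULL
    if (length(tm) > 1) rate <- 1 / median(diff(tm))
  }
  if (ncol(df) != 9L)
    stop("EMG file must have exactly 9 channel columns, found ", ncol(df))
  miss <- setdiff(emgChannels(), colnames(df))
  if (length(miss))
    stop("EMG file is missing channels: ", paste(miss, collapse = ", "))
  m <- as.matrix(df[, emgChannels()])
  if (!is.numeric(m) || anyNA(m))
    stop("EMG file contains non-numeric cells")
  emgTrial(m, rate = rate)
}

#' Write an EMG trial to delimited text
#'
#' @param emg an \linkS4class{EmgTrial}.
#' @param path output path.
#' @param time whether to prepend a seconds-from-start column.
#' @return the path, invisibly.
#' @export
writeEmgTrial <- function(emg, path, time = FALSE) {
  stopifnot(is(emg, "EmgTrial"))
  df <- as.data.frame(emg@signal)
  if (time)
    df <- cbind(time = (seq_len(nrow(df)) - 1) / emg@rate, df)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
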
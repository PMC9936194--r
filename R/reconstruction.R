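# Single- and multi-component reconstruction: rebuild representative
# "fast" and "slow" waveforms from the PCA mean plus loading vectors
# scaled by the 5th/95th percentile scores of the cohort.

#' Empirical percentile of a component's score distribution
#'
#' Linear-interpolation quantile of the subjects' scores on one
#' component (the reconstruction convention for the z05/z95 scaling
#' values).
#'
#' @param model a \linkS4class{WaveformPca}.
#' @param pc component index.
#' @param q quantile in [0, 1].
#' @return the score value.
#' @export
scorePercentile <- function(model, pc, q) {
  stopifnot(is(model, "WaveformPca"))
  if (pc < 1L || pc > ncol(model@scores))
    stop("component ", pc, " is out of range (model has ",
         ncol(model@scores), ")")
  unname(quantile(model@scores[, pc], q, type = 7, names = FALSE))
}

.reconPair <- function(model, pcs, zU, zL, aligned) {
  U <- model@loadings[, pcs, drop = FALSE]
  methods::new("ReconstructionPair",
    upper = as.vector(model@center + U %*% zU),
    lower = as.vector(model@center + U %*% zL),
    center = model@center,
    pcs = as.integer(pcs), zUpper = zU, zLower = zL,
    aligned = aligned, kind = model@kind)
}

#' Single-component reconstruction
#'
#' Upper and lower waveform bounds for one mode of variation:
#' \code{upper = mean + loading * z(qHi)},
#' \code{lower = mean + loading * z(qLo)}. The deviation of either
#' bound from the mean is exactly collinear with the loading, so the
#' pair shows what waveform feature the component scales.
#'
#' @param model a \linkS4class{WaveformPca}.
#' @param pc component index.
#' @param qHi,qLo score percentiles for the two bounds.
#' @return a \linkS4class{ReconstructionPair}.
#' @export
scr <- function(model, pc, qHi = 0.95, qLo = 0.05) {
  zU <- scorePercentile(model, pc, qHi)
  zL <- scorePercentile(model, pc, qLo)
  .reconPair(model, pc, zU, zL, aligned = FALSE)
}

#' Multi-component reconstruction
#'
#' Sums the percentile-scaled deviations of several components about the
#' mean: \code{upper = mean + sum_n loading_n * z_n(qHi)} and likewise
#' with \code{qLo} for the lower bound. With
#' \code{alignToOutcome = TRUE} and a fitted velocity regression,
#' components with negative coefficients contribute their \emph{low}
#' percentile to the upper bound (and vice versa), so the upper
#' reconstruction is the one maximizing predicted velocity ("fast") and
#' the lower one minimizes it ("slow").
#'
#' @param model a \linkS4class{WaveformPca}.
#' @param pcs component indices (nonempty).
#' @param regression optional \linkS4class{StepwiseModel} providing the
#'   coefficient signs for alignment.
#' @param qHi,qLo score percentiles.
#' @param alignToOutcome flip negative-coefficient components so the
#'   upper bound maximizes predicted velocity.
#' @return a \linkS4class{ReconstructionPair}.
#' @export
mcr <- function(model, pcs, regression = NULL, qHi = 0.95, qLo = 0.05,
                alignToOutcome = FALSE) {
  stopifnot(is(model, "WaveformPca"))
  if (!length(pcs)) stop("pcs must name at least one component")
  zHi <- vapply(pcs, function(p) scorePercentile(model, p, qHi), numeric(1L))
  zLo <- vapply(pcs, function(p) scorePercentile(model, p, qLo), numeric(1L))
  if (alignToOutcome) {
    if (is.null(regression))
      stop("alignToOutcome requires the fitted regression model")
    tt <- regression@terms
    sgn <- vapply(pcs, function(p) {
      row <- match(paste0("PC", p), tt$term)
      if (is.na(row)) 1 else sign(tt$estimate[row])
    }, numeric(1L))
    flip <- sgn < 0
    zU <- ifelse(flip, zLo, zHi)
    zL <- ifelse(flip, zHi, zLo)
  } else {
    zU <- zHi
    zL <- zLo
  }
  .reconPair(model, pcs, zU, zL, aligned = alignToOutcome)
}

#' Unflatten a feature vector back into cycle form
#'
#' Exact inverse of the assembly flattening: a 19392-vector becomes a
#' 101 x 64 x 3 kinematic cycle (time x marker x axis); an 18000-vector
#' becomes a 2000 x 9 EMG cycle (time x channel).
#'
#' @param v feature vector.
#' @param kind "kinematic" or "emg"; inferred from the length when
#'   omitted.
#' @return the cycle array/matrix.
#' @export
unflattenFeatures <- function(v, kind = NULL) {
  if (is.null(kind)) {
    kind <- if (length(v) == KIN_FEATURE_LENGTH) "kinematic"
            else if (length(v) == EMG_FEATURE_LENGTH) "emg"
            else stop("feature vector length ", length(v),
                      " matches neither layout (19392 or 18000)")
  }
  if (kind == "kinematic") {
    if (length(v) != KIN_FEATURE_LENGTH)
      stop("kinematic feature vector must have length ", KIN_FEATURE_LENGTH,
           ", got ", length(v))
    arr <- array(v, dim = c(N_KIN_POINTS, 3L, 64L))  # time, axis, marker
    out <- aperm(arr, c(1L, 3L, 2L))
    dimnames(out) <- list(NULL, markerLabels(), c("x", "y", "z"))
    out
  } else {
    if (length(v) != EMG_FEATURE_LENGTH)
      stop("EMG feature vector must have length ", EMG_FEATURE_LENGTH,
           ", got ", length(v))
    matrix(v, nrow = N_EMG_POINTS, dimnames = list(NULL, emgChannels()))
  }
}

setMethod("show", "ReconstructionPair", function(object) {
  cat("ReconstructionPair", if (nzchar(object@kind))
    paste0("(", object@kind, ")"), ": components",
    paste(object@pcs, collapse = ", "),
    if (object@aligned) "[outcome-aligned]", "\n")
  cat(sprintf("  feature length %d; max |upper - lower| = %.4g\n",
              length(object@center), max(abs(object@upper - object@lower))))
})

#' Export a reconstruction pair as avatar / waveform files
#'
#' Kinematic reconstructions are unflattened to 101-frame cycles,
#' rescaled to meters by a reference height, and written as three C3D
#' files (slow, mean, fast). EMG reconstructions are written as one CSV
#' with 2000 rows per bound.
#'
#' @param pair a \linkS4class{ReconstructionPair}.
#' @param dir output directory (created if needed).
#' @param referenceHeight meters; multiplies kinematic features back
#'   into positions for visualization.
#' @param prefix filename prefix.
#' @return character vector of written paths, invisibly.
#' @export
exportReconstruction <- function(pair, dir, referenceHeight = 1.77,
                                 prefix = "recon") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  kind <- if (nzchar(pair@kind)) pair@kind
          else if (length(pair@center) == KIN_FEATURE_LENGTH) "kinematic"
          else "emg"
  paths <- character(0)
  if (kind == "kinematic") {
    for (nm in c("lower", "mean", "upper")) {
      v <- switch(nm, lower = pair@lower, mean = pair@center,
                  upper = pair@upper)
      cyc <- unflattenFeatures(v, "kinematic") * referenceHeight
      p <- file.path(dir, sprintf("%s_%s.c3d", prefix, nm))
      writeC3D(p, cyc, markerLabels(), 60)
      paths <- c(paths, p)
    }
  } else {
    for (nm in c("lower", "mean", "upper")) {
      v <- switch(nm, lower = pair@lower, mean = pair@center,
                  upper = pair@upper)
      p <- file.path(dir, sprintf("%s_%s.csv", prefix, nm))
      write.csv(as.data.frame(unflattenFeatures(v, "emg")), p,
                row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
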
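#' @import methods
#' @importFrom stats approx coef lm pf pt quantile cor cor.test sd spline splinefun var median rnorm runif setNames predict
#' @importFrom utils read.csv write.csv head tail
NULL

#' MarkerTrial: a 3D point-cloud sprint recording
#'
#' Holds the full-body marker trajectories of one sprint trial: a
#' \code{frames x markers x 3} array of positions in meters, the marker
#' labels, the capture rate in Hz, and subject metadata (id, height in
#' meters, binary sex, age in years).
#'
#' The canonical label set has 64 markers and must include \code{T8}
#' (trunk reference used for speed and the 60 m crop), \code{T12}
#' (de-bias reference) and \code{RightAnkle} (stride segmentation).
#'
#' @slot positions numeric array, frames x markers x 3, meters.
#' @slot labels character vector of marker names, one per marker.
#' @slot rate sampling rate in Hz (nominally 60).
#' @slot subject named list with elements \code{id}, \code{height},
#'   \code{sex} (0 = female, 1 = male), \code{age}.
#' @exportClass MarkerTrial
setClass("MarkerTrial",
  representation(
    positions = "array",
    labels    = "character",
    rate      = "numeric",
    subject   = "list"
  )
)

setValidity("MarkerTrial", function(object) {
  d <- dim(object@positions)
  if (length(d) != 3L || d[3] != 3L)
    return("positions must be a frames x markers x 3 array")
  if (d[2] != length(object@labels))
    return("number of markers does not match number of labels")
  if (anyDuplicated(object@labels))
    return("marker labels must be unique")
  if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate <= 0)
    return("rate must be a single positive number")
  if (anyNA(object@positions) || any(!is.finite(object@positions)))
    return("positions contain missing or non-finite values")
  TRUE
})

#' EmgTrial: a multi-channel surface-EMG recording
#'
#' Nine channels in the canonical order GAS, BF, GMAX, GMED, VLO, RF,
#' LES, LD, EO, sampled nominally at 2000 Hz. The \code{normalized} flag
#' records whether amplitudes have been scaled to the dynamic peak
#' reference (dimensionless) or are still in raw units.
#'
#' @slot signal numeric matrix, frames x 9, column names are the
#'   canonical channel names.
#' @slot rate sampling rate in Hz.
#' @slot normalized logical; \code{TRUE} after amplitude normalization.
#' @exportClass EmgTrial
setClass("EmgTrial",
  representation(
    signal     = "matrix",
    rate       = "numeric",
    normalized = "logical"
  )
)

setValidity("EmgTrial", function(object) {
  if (ncol(object@signal) != 9L)
    return("signal must have exactly 9 channels")
  if (!identical(colnames(object@signal), emgChannels()))
    return("channel columns must be in canonical order (GAS, BF, GMAX, GMED, VLO, RF, LES, LD, EO)")
  if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate <= 0)
    return("rate must be a single positive number")
  if (anyNA(object@signal))
    return("signal contains missing values")
  TRUE
})

#' FeatureSet: subjects-by-features waveform matrix with covariates
#'
#' A \linkS4class{SummarizedExperiment} whose single assay
#' (\code{"features"}) stores the flattened waveform features in rows and
#' subjects in columns, with the peak-velocity outcome and the subject
#' covariates (sex, age, height) in \code{colData}. Kinematic feature
#' vectors have 64 x 3 x 101 = 19392 elements; EMG feature vectors have
#' 9 x 2000 = 18000.
#'
#' @slot kind "kinematic" or "emg"; drives flatten/unflatten layout.
#' @exportClass FeatureSet
setClass("FeatureSet",
  contains = "SummarizedExperiment",
  representation(kind = "character")
)

setValidity("FeatureSet", function(object) {
  if (!object@kind %in% c("kinematic", "emg"))
    return("kind must be 'kinematic' or 'emg'")
  cd <- SummarizedExperiment::colData(object)
  need <- c("peakVelocity", "sex", "age", "height")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    return(paste("colData is missing:", paste(miss, collapse = ", ")))
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    return("assay 'features' is required")
  a <- SummarizedExperiment::assay(object, "features")
  if (anyNA(a)) return("feature matrix contains missing values")
  expected <- if (object@kind == "kinematic") 19392L else 18000L
  if (nrow(a) != expected)
    return(sprintf("%s feature vectors must have %d elements, found %d",
                   object@kind, expected, nrow(a)))
  TRUE
})

#' WaveformPca: principal component model of waveform features
#'
#' Column-mean-centered PCA of a subjects x features matrix. Loadings are
#' feature-space unit vectors (one waveform-shaped mode of variation per
#' column); scores are the subjects' coordinates on each mode;
#' \code{varExplained} holds the fraction of total variance per component.
#' Signs follow a deterministic convention: the largest-magnitude element
#' of each loading is positive.
#'
#' @slot center numeric, the feature-space mean vector.
#' @slot loadings features x k matrix with orthonormal columns.
#' @slot scores subjects x k matrix, column means zero.
#' @slot varExplained length-k numeric, nonincreasing, sums to <= 1.
#' @slot kind "kinematic" or "emg" (or "" when fitted on a bare matrix).
#' @exportClass WaveformPca
setClass("WaveformPca",
  representation(
    center       = "numeric",
    loadings     = "matrix",
    scores       = "matrix",
    varExplained = "numeric",
    kind         = "character"
  )
)

setValidity("WaveformPca", function(object) {
  k <- ncol(object@loadings)
  if (ncol(object@scores) != k || length(object@varExplained) != k)
    return("loadings, scores and varExplained disagree on component count")
  if (nrow(object@loadings) != length(object@center))
    return("loadings rows must match center length")
  if (k > 1 && any(diff(object@varExplained) > 1e-12))
    return("varExplained must be nonincreasing")
  if (sum(object@varExplained) > 1 + 1e-8)
    return("varExplained must sum to at most 1")
  TRUE
})

#' StepwiseModel: a stepwise-selected linear model of peak velocity
#'
#' The selected predictors (principal-component scores and/or the sex,
#' age, height covariates) with their OLS estimates, standard errors, t
#' statistics and p-values, plus the model-level summaries: R-squared,
#' root mean squared error (sqrt(SSE / residual df)) and the overall
#' F-test p-value.
#'
#' @slot terms data.frame with columns term, estimate, se, t, p
#'   (intercept row first).
#' @slot r2 numeric R-squared of the final refitted model.
#' @slot rmse numeric residual standard error.
#' @slot modelP overall F-test p-value (NA for intercept-only models).
#' @slot fit the refitted \code{lm} object.
#' @slot selected character vector of selected predictor names.
#' @exportClass StepwiseModel
setClass("StepwiseModel",
  representation(
    terms    = "data.frame",
    r2       = "numeric",
    rmse     = "numeric",
    modelP   = "numeric",
    fit      = "ANY",
    selected = "character"
  )
)

#' ReconstructionPair: upper and lower waveform reconstructions
#'
#' Fast/slow waveform bounds built from the PCA mean plus loading vectors
#' scaled by percentile scores (single- or multi-component
#' reconstruction). With all scores zero both bounds equal the mean.
#'
#' @slot upper,lower,center numeric feature vectors of equal length.
#' @slot pcs integer indices of the components used.
#' @slot zUpper,zLower the score values used per component.
#' @slot aligned logical; TRUE when negative-coefficient components were
#'   flipped so the upper bound maximizes predicted velocity.
#' @slot kind "kinematic", "emg" or "".
#' @exportClass ReconstructionPair
setClass("ReconstructionPair",
  representation(
    upper   = "numeric",
    lower   = "numeric",
    center  = "numeric",
    pcs     = "integer",
    zUpper  = "numeric",
    zLower  = "numeric",
    aligned = "logical",
    kind    = "character"
  )
)

setValidity("ReconstructionPair", function(object) {
  n <- length(object@center)
  if (length(object@upper) != n || length(object@lower) != n)
    return("upper, lower and center must have equal length")
  if (length(object@zUpper) != length(object@pcs) ||
      length(object@zLower) != length(object@pcs))
    return("one score value per component is required")
  TRUE
})

#' CohortSpec: parameters of a synthetic sprint cohort
#'
#' Defines the ground truth for a simulated cohort: how many subjects,
#' how many injected kinematic and EMG modes of variation, which
#' kinematic modes drive peak velocity and how strongly, the sex effect,
#' the velocity noise, the sensor imperfections (linear positional drift
#' and a yaw-misaligned global frame) and the stride rate.
#'
#' @slot nSubjects number of subjects (>= 4).
#' @slot nModesKinematic,nModesEmg number of injected modes per data set.
#' @slot trueCoefficients data.frame with columns \code{mode} (kinematic
#'   mode index) and \code{weight} (m/s per unit score).
#' @slot sexEffect additive velocity effect of sex (m/s; sex coded
#'   0 = female, 1 = male).
#' @slot noiseSdVelocity sd of Gaussian velocity noise (m/s).
#' @slot driftRate linear positional drift (m per second), applied
#'   laterally and identically to all markers.
#' @slot frameYawDeg yaw misalignment of the global frame (degrees).
#' @slot strideRateHz strides per second (> 0).
#' @slot velocityIntercept baseline peak velocity (m/s) for a female
#'   subject with zero mode scores.
#' @slot modeScoreSd per-mode sd of the kinematic mode scores
#'   (dimensionless feature units; recycled to nModesKinematic).
#' @slot seed integer master seed.
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(
    nSubjects         = "integer",
    nModesKinematic   = "integer",
    nModesEmg         = "integer",
    trueCoefficients  = "data.frame",
    sexEffect         = "numeric",
    noiseSdVelocity   = "numeric",
    driftRate         = "numeric",
    frameYawDeg       = "numeric",
    strideRateHz      = "numeric",
    velocityIntercept = "numeric",
    modeScoreSd       = "numeric",
    seed              = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  if (object@nSubjects < 4L) return("nSubjects must be >= 4")
  if (object@noiseSdVelocity < 0) return("noiseSdVelocity must be >= 0")
  if (object@strideRateHz <= 0) return("strideRateHz must be > 0")
  if (object@nModesKinematic < 0L || object@nModesEmg < 0L)
    return("mode counts must be nonnegative")
  tc <- object@trueCoefficients
  if (nrow(tc)) {
    if (!all(c("mode", "weight") %in% colnames(tc)))
      return("trueCoefficients needs columns 'mode' and 'weight'")
    if (any(tc$mode < 1 | tc$mode > object@nModesKinematic))
      return("trueCoefficients refers to a kinematic mode that is not generated")
  }
  if (length(object@modeScoreSd) != object@nModesKinematic)
    return("modeScoreSd must have one entry per kinematic mode")
  if (any(object@modeScoreSd <= 0)) return("modeScoreSd must be positive")
  TRUE
})
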
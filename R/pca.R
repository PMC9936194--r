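# Waveform PCA: each retained component is itself a waveform-shaped
# mode of variation of the flattened cycle features; subjects' scores
# on those modes are the inputs to the velocity regression.

#' Construct a FeatureSet
#'
#' Bundles the subjects-by-features waveform matrix with the
#' peak-velocity outcome and the subject covariates into a
#' \linkS4class{SummarizedExperiment}-backed container (features in
#' rows, subjects in columns).
#'
#' @param features subjects x features numeric matrix (19392 columns
#'   for kinematic, 18000 for EMG).
#' @param peakVelocity per-subject peak sprint velocity, m/s.
#' @param sex per-subject binary covariate (0 = female, 1 = male).
#' @param age per-subject age, years.
#' @param height per-subject height, meters.
#' @param kind "kinematic" or "emg".
#' @param subjectIds optional subject identifiers.
#' @return a \linkS4class{FeatureSet}.
#' @export
featureSet <- function(features, peakVelocity, sex, age, height,
                       kind = c("kinematic", "emg"), subjectIds = NULL) {
  kind <- match.arg(kind)
  features <- as.matrix(features)
  n <- nrow(features)
  if (is.null(subjectIds)) subjectIds <- sprintf("S%02d", seq_len(n))
  cd <- S4Vectors::DataFrame(peakVelocity = peakVelocity, sex = sex,
                             age = age, height = height,
                             row.names = subjectIds)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(features)), colData = cd)
  methods::new("FeatureSet", se, kind = kind)
}

#' @rdname FeatureSet-class
#' @param object a \linkS4class{FeatureSet}.
#' @export
setMethod("featureMatrix", "FeatureSet", function(object) {
  t(SummarizedExperiment::assay(object, "features"))
})

#' @rdname FeatureSet-class
#' @export
setMethod("peakVelocity", "FeatureSet", function(object) {
  SummarizedExperiment::colData(object)$peakVelocity
})

setMethod("show", "FeatureSet", function(object) {
  a <- SummarizedExperiment::assay(object, "features")
  cat("FeatureSet (", object@kind, "): ", ncol(a), " subjects x ", nrow(a),
      " features\n", sep = "")
  v <- peakVelocity(object)
  cat(sprintf("  peak velocity: %.2f +/- %.2f m/s\n", mean(v), sd(v)))
})

#' Fit a waveform PCA
#'
#' Column-mean-centers the subjects x features matrix and decomposes it
#' by SVD. Columns are centered but not scaled: all features within a
#' matrix share units, and scaling would distort the waveform geometry.
#' The number of components is \code{min(subjects - 1, features)}.
#' Signs are made deterministic by requiring the largest-magnitude
#' element of each loading to be positive (scores are flipped to
#' match), so repeated fits are bit-identical.
#'
#' @param x a \linkS4class{FeatureSet} or a subjects x features matrix.
#' @return a \linkS4class{WaveformPca}.
#' @export
fitWaveformPca <- function(x) {
  kind <- ""
  if (is(x, "FeatureSet")) {
    kind <- x@kind
    x <- featureMatrix(x)
  }
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) stop("at least 2 subjects are required")
  if (!all(is.finite(x))) stop("feature matrix contains non-finite values")
  center <- colMeans(x)
  xc <- sweep(x, 2L, center, "-")
  total <- sum(xc^2)
  if (total < 1e-300)
    stop("feature matrix has zero variance; PCA is undefined")
  k <- min(n - 1L, ncol(x))
  sv <- svd(xc, nu = k, nv = k)
  d <- sv$d[seq_len(k)]
  loadings <- sv$v
  scores <- sv$u %*% diag(d, k, k)
  # deterministic sign convention
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  colnames(loadings) <- colnames(scores) <- paste0("PC", seq_len(k))
  methods::new("WaveformPca", center = center, loadings = loadings,
               scores = scores, varExplained = d^2 / sum(sv$d^2),
               kind = kind)
}

#' @rdname WaveformPca-class
#' @param object a \linkS4class{WaveformPca}.
#' @export
setMethod("pcaCenter", "WaveformPca", function(object) object@center)

#' @rdname WaveformPca-class
#' @export
setMethod("pcaLoadings", "WaveformPca", function(object) object@loadings)

#' @rdname WaveformPca-class
#' @export
setMethod("pcaScores", "WaveformPca", function(object) object@scores)

#' @rdname WaveformPca-class
#' @export
setMethod("varExplained", "WaveformPca", function(object) object@varExplained)

setMethod("show", "WaveformPca", function(object) {
  k <- ncol(object@loadings)
  cat("WaveformPca", if (nzchar(object@kind)) paste0("(", object@kind, ")"),
      ": ", nrow(object@scores), " subjects, ", k, " components\n", sep = "")
  nshow <- min(5L, k)
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * object@varExplained[seq_len(nshow)]),
            collapse = ", "),
      if (k > nshow) "...", "\n")
})

#' Retain components to a cumulative variance threshold
#'
#' Returns the smallest leading prefix of components whose cumulative
#' explained variance exceeds \code{threshold} (default 0.95, i.e.
#' components explaining more than 95\% of the variance are retained).
#'
#' @param model a \linkS4class{WaveformPca}.
#' @param threshold cumulative variance fraction to exceed.
#' @return list with \code{indices} (1..k) and \code{cumulative}
#'   (variance fraction achieved).
#' @export
retainComponents <- function(model, threshold = 0.95) {
  stopifnot(is(model, "WaveformPca"))
  cum <- cumsum(model@varExplained)
  k <- which(cum > threshold)
  k <- if (length(k)) k[1L] else length(cum)
  list(indices = seq_len(k), cumulative = cum[k])
}

#' Project feature vectors onto a fitted PCA
#'
#' @param model a \linkS4class{WaveformPca}.
#' @param x subjects x features matrix (or a single feature vector).
#' @return subjects x components score matrix.
#' @export
projectScores <- function(model, x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  sweep(x, 2L, model@center, "-") %*% model@loadings
}

#' Reconstruct feature vectors from scores
#'
#' @param model a \linkS4class{WaveformPca}.
#' @param scores subjects x components matrix (or a single score row);
#'   may cover a subset \code{pcs} of components.
#' @param pcs component indices matching the columns of \code{scores}.
#' @return subjects x features matrix.
#' @export
reconstructFeatures <- function(model, scores, pcs = seq_len(ncol(model@loadings))) {
  if (is.vector(scores)) scores <- matrix(scores, nrow = 1L)
  sweep(scores %*% t(model@loadings[, pcs, drop = FALSE]), 2L,
        model@center, "+")
}
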
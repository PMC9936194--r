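#' @rdname MarkerTrial-class
#' @param object a \linkS4class{MarkerTrial}, \linkS4class{EmgTrial} or
#'   model object.
#' @export
setGeneric("trialPositions", function(object) standardGeneric("trialPositions"))

#' @rdname MarkerTrial-class
#' @export
setGeneric("trialRate", function(object) standardGeneric("trialRate"))

#' @rdname MarkerTrial-class
#' @export
setGeneric("trialSubject", function(object) standardGeneric("trialSubject"))

#' @rdname MarkerTrial-class
#' @export
setGeneric("trialLabels", function(object) standardGeneric("trialLabels"))

#' @rdname EmgTrial-class
#' @export
setGeneric("emgSignal", function(object) standardGeneric("emgSignal"))

#' @rdname EmgTrial-class
#' @export
setGeneric("isNormalized", function(object) standardGeneric("isNormalized"))

#' @rdname WaveformPca-class
#' @export
setGeneric("pcaCenter", function(object) standardGeneric("pcaCenter"))

#' @rdname WaveformPca-class
#' @export
setGeneric("pcaLoadings", function(object) standardGeneric("pcaLoadings"))

#' @rdname WaveformPca-class
#' @export
setGeneric("pcaScores", function(object) standardGeneric("pcaScores"))

#' @rdname WaveformPca-class
#' @export
setGeneric("varExplained", function(object) standardGeneric("varExplained"))

#' @rdname StepwiseModel-class
#' @export
setGeneric("modelTerms", function(object) standardGeneric("modelTerms"))

#' @rdname StepwiseModel-class
#' @export
setGeneric("selectedTerms", function(object) standardGeneric("selectedTerms"))

#' @rdname FeatureSet-class
#' @export
setGeneric("featureMatrix", function(object) standardGeneric("featureMatrix"))

#' @rdname FeatureSet-class
#' @export
setGeneric("peakVelocity", function(object) standardGeneric("peakVelocity"))
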
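#' @rdname BioRecording-class
#' @param object,x an object.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname BioRecording-class
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname BioRecording-class
#' @export
setGeneric("channelRoles", function(x) standardGeneric("channelRoles"))

#' @rdname BioRecording-class
#' @export
setGeneric("channelSignal", function(x, role) standardGeneric("channelSignal"))

#' @rdname BioRecording-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname StimulusSchedule-class
#' @export
setGeneric("stimulusEvents", function(x) standardGeneric("stimulusEvents"))

#' @rdname StimulusSchedule-class
#' @export
setGeneric("baselineOnsets", function(x) standardGeneric("baselineOnsets"))

#' @rdname LabeledWindowSet-class
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname EvalReport-class
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))

#' @rdname EvalReport-class
#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))

#' @rdname EvalReport-class
#' @export
setGeneric("sensitivity", function(x) standardGeneric("sensitivity"))

#' @rdname EvalReport-class
#' @export
setGeneric("specificity", function(x) standardGeneric("specificity"))

#' @rdname EvalReport-class
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))

#' @rdname EvalReport-class
#' @export
setGeneric("svmParams", function(x) standardGeneric("svmParams"))
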
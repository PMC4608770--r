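#' @describeIn BioRecording-class sampling rate in Hz.
#' @export
setMethod("samplingRate", "BioRecording", function(x) x@fs)

#' @describeIn LabeledWindowSet-class sampling rate in Hz.
#' @export
setMethod("samplingRate", "LabeledWindowSet", function(x) x@fs)

#' @describeIn BioRecording-class subject identifier.
#' @export
setMethod("subjectId", "BioRecording", function(x) x@subjectId)

#' @describeIn LabeledWindowSet-class subject identifier.
#' @export
setMethod("subjectId", "LabeledWindowSet", function(x) x@subjectId)

#' @describeIn BioRecording-class named character of channel roles.
#' @export
setMethod("channelRoles", "BioRecording", function(x) x@channelRole)

#' @describeIn BioRecording-class sample vector of the channel with a role.
#' @param role one of "emg_zyg", "emg_cor", "emg_tra", "scl", "ecg".
#' @export
setMethod("channelSignal", "BioRecording", function(x, role) {
  nm <- names(x@channelRole)[match(role, x@channelRole)]
  if (is.na(nm)) stop("no channel with role '", role, "'")
  x@channels[[nm]]
})

#' @describeIn BioRecording-class samples per channel.
#' @export
setMethod("nSamples", "BioRecording", function(x) {
  if (length(x@channels)) length(x@channels[[1L]]) else 0L
})

#' @describeIn StimulusSchedule-class event table (level, onset_s, plateau_s).
#' @export
setMethod("stimulusEvents", "StimulusSchedule", function(x) x@events)

#' @describeIn StimulusSchedule-class baseline-window onsets in seconds.
#' @export
setMethod("baselineOnsets", "StimulusSchedule", function(x) x@baselineOnsets)

#' @describeIn LabeledWindowSet-class window class labels (factor B, T1..T4).
#' @export
setMethod("classLabels", "LabeledWindowSet", function(x) x@labels)

#' @describeIn PainFeatureMatrix-class window class labels.
#' @export
setMethod("classLabels", "PainFeatureMatrix", function(x)
  factor(as.character(colData(x)$class_label), levels = .CLASS_LEVELS))

#' @describeIn EvalReport-class classification accuracy.
#' @export
setMethod("accuracy", "EvalReport", function(x) x@accuracy)

#' @describeIn EvalReport-class confusion matrix, predicted x true.
#' @export
setMethod("confusionMatrix", "EvalReport", function(x) x@confusion)

#' @describeIn EvalReport-class per-class sensitivity.
#' @export
setMethod("sensitivity", "EvalReport", function(x) x@sensitivity)

#' @describeIn EvalReport-class per-class specificity.
#' @export
setMethod("specificity", "EvalReport", function(x) x@specificity)

#' @describeIn EvalReport-class ordered forward-selected features.
#' @export
setMethod("selectedFeatures", "EvalReport", function(x) x@selectedFeatures)

#' @describeIn EvalReport-class tuned c(C, gamma).
#' @export
setMethod("svmParams", "EvalReport", function(x) x@svmParams)

setMethod("show", "BioRecording", function(object) {
  cat("BioRecording | subject", object@subjectId,
      "|", length(object@channels), "channels x",
      nSamples(object), "samples @", object@fs, "Hz\n")
  cat("  roles:", paste(object@channelRole, collapse = ", "), "\n")
})

setMethod("show", "StimulusSchedule", function(object) {
  tab <- table(object@events$level)
  cat("StimulusSchedule |", nrow(object@events), "stimuli (",
      paste(names(tab), tab, sep = ":", collapse = " "), ") +",
      length(object@baselineOnsets), "baseline windows\n")
})

setMethod("show", "LabeledWindowSet", function(object) {
  cat("LabeledWindowSet | subject", object@subjectId, "|",
      length(object@labels), "windows of", object@windowS, "s @",
      object@fs, "Hz\n")
  print(table(object@labels))
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport |", object@task, "| accuracy",
      sprintf("%.4f", object@accuracy), "| Cramer's V",
      sprintf("%.3f (%s)", object@cramersV, object@band), "\n")
  cat("  SVM C =", object@svmParams[["C"]],
      " gamma =", object@svmParams[["gamma"]], "|",
      length(object@selectedFeatures), "selected features\n")
})

setMethod("show", "SelectionResult", function(object) {
  cat("SelectionResult |", length(object@kept), "kept |",
      length(object@droppedStatic), "static |",
      nrow(object@droppedCorrelated), "correlated dropped\n")
})
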
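#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

## Channel roles of the standard five-channel montage and the display names
## used to build feature identifiers ("Zygomaticus_Similarity_Correlation").
.STANDARD_ROLES <- c("emg_zyg", "emg_cor", "emg_tra", "scl", "ecg")
.ROLE_DISPLAY <- c(emg_zyg = "Zygomaticus", emg_cor = "Corrugator",
                   emg_tra = "Trapezius", scl = "SCL", ecg = "ECG")
.CLASS_LEVELS <- c("B", "T1", "T2", "T3", "T4")

#' Multichannel biopotential recording
#'
#' A single subject's synchronous biopotential recording: an ordered set of
#' equal-length sample vectors (one per channel), a common sampling rate and a
#' mapping of each channel onto its physiological role. The standard montage
#' has five roles: zygomaticus, corrugator and trapezius surface EMG, skin
#' conductance level (SCL) and ECG.
#'
#' @slot subjectId character(1), opaque subject identifier.
#' @slot fs numeric(1), sampling rate in Hz (> 0).
#' @slot channels named list of numeric vectors, all of identical length.
#' @slot channelRole named character, channel name -> role, roles drawn from
#'   \code{c("emg_zyg", "emg_cor", "emg_tra", "scl", "ecg")}.
#'
#' @seealso [readRecording()], [simulateSubject()]
#' @exportClass BioRecording
setClass("BioRecording",
  representation(subjectId = "character", fs = "numeric",
                 channels = "list", channelRole = "character"))

setValidity("BioRecording", function(object) {
  msg <- character(0)
  if (length(object@subjectId) != 1L) msg <- c(msg, "subjectId must be length 1")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single strictly positive number")
  n <- lengths(object@channels)
  if (length(n) && length(unique(n)) != 1L)
    msg <- c(msg, "all channels must have equal length")
  if (is.null(names(object@channels)) ||
      !setequal(names(object@channels), names(object@channelRole)))
    msg <- c(msg, "channels and channelRole must share the same names")
  bad <- setdiff(object@channelRole, .STANDARD_ROLES)
  if (length(bad))
    msg <- c(msg, paste0("unknown channel role(s): ", paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Stimulus schedule of the phasic heat protocol
#'
#' The event list of one experimental run: phasic heat stimuli at four
#' calibrated intensities (T1 pain threshold ... T4 pain tolerance), each held
#' for a 4 s plateau and separated by randomized 8-12 s pauses, plus onsets of
#' stimulus-free baseline ("non-pain") windows. The standard protocol applies
#' each level 20 times in randomized order (80 stimuli) and provides 20
#' baseline windows.
#'
#' @slot events data.frame with columns \code{level} (character, one of
#'   T1..T4), \code{onset_s}, \code{plateau_s} (numeric, seconds).
#' @slot baselineOnsets numeric, onsets (s) of baseline windows (class B).
#' @slot baselineTempC numeric(1), baseline temperature (deg C), 32 by default.
#' @slot pauseRange numeric(2), bounds of the randomized inter-stimulus pause.
#'
#' @seealso [generateSchedule()], [readSchedule()], [cutWindows()]
#' @exportClass StimulusSchedule
setClass("StimulusSchedule",
  representation(events = "data.frame", baselineOnsets = "numeric",
                 baselineTempC = "numeric", pauseRange = "numeric"),
  prototype(baselineTempC = 32, pauseRange = c(8, 12)))

setValidity("StimulusSchedule", function(object) {
  ev <- object@events
  msg <- character(0)
  if (!all(c("level", "onset_s", "plateau_s") %in% names(ev)))
    return("events must have columns level, onset_s, plateau_s")
  if (nrow(ev)) {
    if (!all(ev$level %in% c("T1", "T2", "T3", "T4")))
      msg <- c(msg, "event levels must be T1..T4")
    if (any(ev$onset_s < 0)) msg <- c(msg, "event onsets must be >= 0")
    o <- order(ev$onset_s)
    ends <- ev$onset_s[o] + ev$plateau_s[o]
    if (nrow(ev) > 1L && any(ev$onset_s[o][-1L] < ends[-nrow(ev)]))
      msg <- c(msg, "stimulus events overlap within their plateaus")
  }
  if (any(object@baselineOnsets < 0)) msg <- c(msg, "baseline onsets must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Set of labelled analysis windows
#'
#' Fixed-length (default 5.5 s) multichannel segments cut from a recording:
#' one "pain window" per stimulus, labelled by its level, and one "non-pain
#' window" per baseline onset (class B). Segments are stored channel-wise as
#' sample-by-window matrices. Beat times from QRS detection on the full
#' recording are carried along so RR features can be computed per window.
#'
#' @slot subjectId character(1).
#' @slot fs numeric(1), sampling rate in Hz.
#' @slot windowS numeric(1), window length in seconds.
#' @slot labels factor with levels B, T1..T4, one per window.
#' @slot onsets numeric, window onsets (s), one per window.
#' @slot channels named list (by role) of numeric matrices, samples x windows.
#' @slot beatTimes numeric, QRS beat times (s) over the whole recording.
#'
#' @seealso [cutWindows()], [extractFeatures()]
#' @exportClass LabeledWindowSet
setClass("LabeledWindowSet",
  representation(subjectId = "character", fs = "numeric", windowS = "numeric",
                 labels = "factor", onsets = "numeric", channels = "list",
                 beatTimes = "numeric"))

setValidity("LabeledWindowSet", function(object) {
  msg <- character(0)
  nw <- length(object@labels)
  if (length(object@onsets) != nw) msg <- c(msg, "labels and onsets differ in length")
  if (!all(levels(object@labels) %in% .CLASS_LEVELS))
    msg <- c(msg, "labels must use levels B, T1..T4")
  dims <- vapply(object@channels, function(m) ncol(m), integer(1))
  if (length(dims) && any(dims != nw))
    msg <- c(msg, "each channel matrix must have one column per window")
  ns <- vapply(object@channels, function(m) nrow(m), integer(1))
  if (length(ns) && length(unique(ns)) != 1L)
    msg <- c(msg, "all channel segments must have the same sample count")
  if (length(msg)) msg else TRUE
})

#' Feature matrix of labelled windows
#'
#' A \linkS4class{SummarizedExperiment} holding the extracted feature space:
#' features in rows (159 under the standard five-channel configuration),
#' windows in columns, with \code{subject_id} and \code{class_label} in
#' \code{colData} and the feature group in \code{rowData$group}.
#'
#' @seealso [extractFeatures()], [znormPerPerson()], [writeFeatureMatrix()]
#' @exportClass PainFeatureMatrix
setClass("PainFeatureMatrix", contains = "SummarizedExperiment")

setValidity("PainFeatureMatrix", function(object) {
  msg <- character(0)
  cd <- colData(object)
  if (!all(c("subject_id", "class_label") %in% names(cd)))
    return("colData must contain subject_id and class_label")
  if (!all(as.character(cd$class_label) %in% .CLASS_LEVELS))
    msg <- c(msg, "class_label values must be in B, T1..T4")
  if (!"features" %in% assayNames(object))
    msg <- c(msg, "assay 'features' is required")
  if (length(msg)) msg else TRUE
})

#' Classifier evaluation report
#'
#' Confusion matrix and derived statistics of one classification task:
#' accuracy (correct test vectors / all test vectors), per-class sensitivity
#' and specificity (one-vs-others for more than two classes), Cramer's V with
#' its association band, the ordered list of forward-selected features, and
#' the tuned RBF-SVM hyperparameters.
#'
#' @slot task character(1), task identifier (e.g. "B_vs_T4").
#' @slot confusion matrix of counts, predicted (rows) x true (columns).
#' @slot accuracy numeric(1) in [0, 1].
#' @slot sensitivity named numeric, per class.
#' @slot specificity named numeric, per class.
#' @slot cramersV numeric(1) in [0, 1] (NA for degenerate tables).
#' @slot band character(1), association-strength label for \code{cramersV}.
#' @slot selectedFeatures character, ordered as selected.
#' @slot svmParams named numeric, \code{c(C = ..., gamma = ...)}.
#' @slot trace data.frame, forward-selection trace (round, feature, cv_accuracy).
#'
#' @seealso [evaluateModel()], [runTask()], [cramersV()]
#' @exportClass EvalReport
setClass("EvalReport",
  representation(task = "character", confusion = "matrix", accuracy = "numeric",
                 sensitivity = "numeric", specificity = "numeric",
                 cramersV = "numeric", band = "character",
                 selectedFeatures = "character", svmParams = "numeric",
                 trace = "data.frame"))

setValidity("EvalReport", function(object) {
  msg <- character(0)
  if (length(object@accuracy) == 1L && is.finite(object@accuracy)) {
    if (object@accuracy < 0 || object@accuracy > 1)
      msg <- c(msg, "accuracy must lie in [0, 1]")
    n <- sum(object@confusion)
    if (n > 0 && abs(sum(diag(object@confusion)) / n - object@accuracy) > 1e-8)
      msg <- c(msg, "accuracy must equal trace(confusion)/total")
  }
  if (length(msg)) msg else TRUE
})

#' Result of the two-stage feature selection
#'
#' @slot kept character, retained features in canonical order (pruning) or in
#'   selection order (forward selection).
#' @slot droppedStatic character, features removed as static/degenerate.
#' @slot droppedCorrelated data.frame with columns \code{dropped},
#'   \code{kept_partner}, \code{r}.
#' @slot trace data.frame, forward-selection trace with columns \code{round},
#'   \code{feature}, \code{cv_accuracy}.
#'
#' @seealso [pruneStatic()], [pruneCorrelated()], [forwardSelect()]
#' @exportClass SelectionResult
setClass("SelectionResult",
  representation(kept = "character", droppedStatic = "character",
                 droppedCorrelated = "data.frame", trace = "data.frame"))
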
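#' Construct a BioRecording
#'
#' @param subjectId character(1).
#' @param fs sampling rate in Hz.
#' @param channels named list of equal-length numeric vectors.
#' @param roles named character mapping channel names to roles; defaults to
#'   taking the channel names themselves as roles (the standard montage).
#' @return A validated \linkS4class{BioRecording}.
#' @examples
#' r <- bioRecording("s1", 512, list(ecg = sin(1:512), scl = rep(5, 512),
#'   emg_zyg = rnorm(512), emg_cor = rnorm(512), emg_tra = rnorm(512)))
#' @export
bioRecording <- function(subjectId, fs, channels, roles = NULL) {
  if (is.null(roles)) roles <- stats::setNames(names(channels), names(channels))
  new("BioRecording", subjectId = as.character(subjectId), fs = fs,
      channels = channels, channelRole = roles)
}

#' Construct a StimulusSchedule
#'
#' @param events data.frame with columns level, onset_s, plateau_s.
#' @param baselineOnsets numeric vector of baseline-window onsets (s).
#' @param baselineTempC baseline temperature, default 32.
#' @param pauseRange inter-stimulus pause bounds, default c(8, 12).
#' @return A validated \linkS4class{StimulusSchedule}.
#' @export
stimulusSchedule <- function(events, baselineOnsets = numeric(0),
                             baselineTempC = 32, pauseRange = c(8, 12)) {
  events <- as.data.frame(events)
  if (nrow(events)) {
    events$level <- as.character(events$level)
    events <- events[order(events$onset_s), , drop = FALSE]
    rownames(events) <- NULL
  }
  new("StimulusSchedule", events = events,
      baselineOnsets = as.numeric(baselineOnsets),
      baselineTempC = baselineTempC, pauseRange = pauseRange)
}

#' Read / write a multichannel recording
#'
#' The on-disk format is a plain-text pair: a signals CSV with a \code{time_s}
#' column plus one column per channel, and a metadata JSON giving
#' \code{subject_id}, \code{fs} (Hz) and the channel-to-role map. Times are in
#' seconds; values are written at full precision so a write/read round trip is
#' exact.
#'
#' @param pathSignals path of the signals CSV.
#' @param pathMeta path of the metadata JSON.
#' @return \code{readRecording} returns a \linkS4class{BioRecording};
#'   \code{writeRecording} invisibly returns the signal path.
#' @export
readRecording <- function(pathSignals, pathMeta) {
  meta <- jsonlite::read_json(pathMeta, simplifyVector = TRUE)
  df <- utils::read.csv(pathSignals, check.names = FALSE)
  if (!"time_s" %in% names(df)) stop("signals CSV must have a time_s column")
  chn <- setdiff(names(df), "time_s")
  roles <- unlist(meta$roles)
  missing <- setdiff(names(roles), chn)
  if (length(missing))
    stop("channels in metadata missing from CSV: ", paste(missing, collapse = ", "))
  missingRole <- setdiff(.STANDARD_ROLES, roles)
  if (length(missingRole))
    stop("recording metadata lacks required role(s): ",
         paste(missingRole, collapse = ", "))
  channels <- lapply(df[chn], as.numeric)
  bioRecording(meta$subject_id, as.numeric(meta$fs), channels, roles[chn])
}

#' @rdname readRecording
#' @param x a \linkS4class{BioRecording}.
#' @export
writeRecording <- function(x, pathSignals, pathMeta) {
  stopifnot(is(x, "BioRecording"))
  n <- nSamples(x)
  df <- data.frame(time_s = (seq_len(n) - 1L) / x@fs)
  for (nm in names(x@channels)) df[[nm]] <- x@channels[[nm]]
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                   pathSignals, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(subject_id = x@subjectId, fs = x@fs,
                            roles = as.list(x@channelRole)),
                       pathMeta, auto_unbox = TRUE, digits = NA)
  invisible(pathSignals)
}

#' Read / write a stimulus schedule
#'
#' Events CSV with columns \code{level,onset_s,plateau_s}; rows with level
#' \code{B} denote baseline ("non-pain") window onsets and carry no plateau.
#' An empty file (header only) yields an empty schedule.
#'
#' @param path CSV path.
#' @return \code{readSchedule} returns a \linkS4class{StimulusSchedule}.
#' @export
readSchedule <- function(path) {
  df <- utils::read.csv(path, colClasses = c(level = "character"))
  isB <- df$level == "B"
  stimulusSchedule(df[!isB, c("level", "onset_s", "plateau_s")],
                   baselineOnsets = df$onset_s[isB])
}

#' @rdname readSchedule
#' @param x a \linkS4class{StimulusSchedule}.
#' @export
writeSchedule <- function(x, path) {
  stopifnot(is(x, "StimulusSchedule"))
  ev <- x@events
  df <- rbind(
    if (nrow(ev)) data.frame(level = ev$level, onset_s = ev$onset_s,
                             plateau_s = ev$plateau_s),
    if (length(x@baselineOnsets))
      data.frame(level = "B", onset_s = x@baselineOnsets, plateau_s = NA_real_))
  if (is.null(df)) df <- data.frame(level = character(0), onset_s = numeric(0),
                                    plateau_s = numeric(0))
  df <- df[order(df$onset_s), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a PainFeatureMatrix
#'
#' @param values numeric matrix, features (rows) x windows (columns).
#' @param subjects character vector, one subject id per window.
#' @param labels character or factor, one class label (B, T1..T4) per window.
#' @param group optional character vector of feature-group names per row.
#' @return A validated \linkS4class{PainFeatureMatrix}.
#' @export
painFeatureMatrix <- function(values, subjects, labels, group = NULL) {
  labels <- factor(as.character(labels), levels = .CLASS_LEVELS)
  if (anyNA(labels)) stop("class labels must be in B, T1..T4")
  rd <- if (is.null(group)) S4Vectors::DataFrame(row.names = rownames(values))
        else S4Vectors::DataFrame(group = group, row.names = rownames(values))
  se <- SummarizedExperiment(
    assays = list(features = values),
    colData = S4Vectors::DataFrame(subject_id = as.character(subjects),
                                   class_label = labels),
    rowData = rd)
  new("PainFeatureMatrix", se)
}

#' Read / write a feature matrix
#'
#' Tab-separated text: one row per window, first two columns
#' \code{subject_id} and \code{class_label}, then one column per feature in
#' canonical order, written at full precision.
#'
#' @param path TSV path.
#' @return \code{readFeatureMatrix} returns a
#'   \linkS4class{PainFeatureMatrix}.
#' @export
readFeatureMatrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c(subject_id = "character",
                                         class_label = "character"))
  feat <- setdiff(names(df), c("subject_id", "class_label"))
  vals <- t(as.matrix(df[feat]))
  rownames(vals) <- feat
  painFeatureMatrix(vals, df$subject_id, df$class_label,
                    group = featureGroupOf(feat))
}

#' @rdname readFeatureMatrix
#' @param x a \linkS4class{PainFeatureMatrix}.
#' @export
writeFeatureMatrix <- function(x, path) {
  stopifnot(is(x, "PainFeatureMatrix"))
  vals <- t(assay(x, "features"))
  df <- data.frame(subject_id = colData(x)$subject_id,
                   class_label = as.character(colData(x)$class_label),
                   check.names = FALSE)
  for (j in seq_len(ncol(vals))) df[[colnames(vals)[j]]] <- vals[, j]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  body <- do.call(paste, c(lapply(df, function(col) {
    if (is.numeric(col)) formatC(col, digits = 17, format = "g") else col
  }), sep = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' Read / write an evaluation report
#'
#' JSON serialization of an \linkS4class{EvalReport}: confusion matrix,
#' accuracy, per-class sensitivity/specificity, Cramer's V and band, selected
#' features and SVM hyperparameters.
#'
#' @param path JSON path.
#' @return \code{readEvalReport} returns an \linkS4class{EvalReport}.
#' @export
readEvalReport <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  conf <- as.matrix(j$confusion)
  storage.mode(conf) <- "double"
  dimnames(conf) <- list(predicted = j$classes, true = j$classes)
  new("EvalReport", task = j$task, confusion = conf, accuracy = j$accuracy,
      sensitivity = unlist(j$sensitivity), specificity = unlist(j$specificity),
      cramersV = j$cramers_v, band = j$band,
      selectedFeatures = as.character(j$selected_features),
      svmParams = c(C = j$svm_params$C, gamma = j$svm_params$gamma),
      trace = if (length(j$trace)) as.data.frame(j$trace) else
        data.frame(round = integer(0), feature = character(0),
                   cv_accuracy = numeric(0)))
}

#' @rdname readEvalReport
#' @param x an \linkS4class{EvalReport}.
#' @export
writeEvalReport <- function(x, path) {
  stopifnot(is(x, "EvalReport"))
  jsonlite::write_json(list(
    task = x@task, classes = rownames(x@confusion),
    confusion = lapply(seq_len(nrow(x@confusion)),
                       function(i) unname(x@confusion[i, ])),
    accuracy = x@accuracy,
    sensitivity = as.list(x@sensitivity), specificity = as.list(x@specificity),
    cramers_v = x@cramersV, band = x@band,
    selected_features = x@selectedFeatures,
    svm_params = list(C = unname(x@svmParams["C"]),
                      gamma = unname(x@svmParams["gamma"])),
    trace = x@trace), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
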
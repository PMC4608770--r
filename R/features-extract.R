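## Canonical feature-name table for the standard five-channel configuration:
## 4 waveform channels x 39 features + 3 ECG RR features = 159.
.GROUP_FEATURES <- list(
  Amplitude = c(peak = "Peak", p2p = "PeakToPeak", rms = "RootMeanSquare",
                mlocmaxv = "MeanLocalMaxima", minlocminv = "MeanLocalMinima",
                mav = "MeanAbsoluteValue", mavfd = "MeanAbsValueFirstDiff",
                mavfdn = "MeanAbsValueFirstDiffNorm",
                mavsd = "MeanAbsValueSecondDiff",
                mavsdn = "MeanAbsValueSecondDiffNorm"),
  Frequency = c(zc = "ZeroCrossings", fmode = "ModeFrequency",
                bw = "Bandwidth", cf = "CentralFrequency",
                fmean = "MeanFrequency", fmed = "MedianFrequency"),
  Stationarity = c(median = "Median", freqpond = "FrequencyWeighted",
                   area = "Area", area_ponderada = "WeightedArea",
                   me = "StandardDeviationOfMeanVector",
                   sd = "StandardDeviationOfStdVector"),
  Entropy = c(aprox = "Approximate", fuzzy = "Fuzzy", sample = "Sample",
              shannon = "Shannon", spectral = "Spectral"),
  Linearity = c(ldf = "LagDependenceValues",
                pldf = "PolynomialLagDependenceValues"),
  Variability = c(var = "Variance", std = "StandardDeviation",
                  range = "Range", intrange = "SemiInterquartileRange"),
  Similarity = c(cohe_f_median = "CoherenceAtMedianFrequency",
                 cohe_mean = "CoherenceMean",
                 cohe_pond_mean = "CoherenceWeightedMean",
                 cohe_area_pond = "CoherenceWeightedArea",
                 corr = "Correlation", mutinfo = "MutualInformation"))
.RR_FEATURES <- c(meanRR = "MeanRR", rmssd = "RMSSD", slopeRR = "SlopeRR")

#' Canonical feature names
#'
#' The fixed column order of the extracted feature space: for each waveform
#' channel (zygomaticus, corrugator, trapezius EMG, SCL) the 39 features of
#' the amplitude, frequency, stationarity, entropy, linearity, variability
#' and similarity groups, then the three ECG RR features - 159 names in the
#' standard configuration, formatted \code{Channel_Group_Feature}.
#'
#' @param roles character, channel roles to include (default the standard
#'   five).
#' @return data.frame with columns \code{name}, \code{role}, \code{group},
#'   \code{feature}.
#' @examples
#' nrow(painFeatureNames())   # 159
#' @export
painFeatureNames <- function(roles = .STANDARD_ROLES) {
  rows <- list()
  for (role in setdiff(roles, "ecg")) {
    disp <- .ROLE_DISPLAY[[role]]
    for (grp in names(.GROUP_FEATURES)) {
      feats <- .GROUP_FEATURES[[grp]]
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste(disp, grp, feats, sep = "_"),
        role = role, group = grp, feature = names(feats))
    }
  }
  if ("ecg" %in% roles)
    rows[[length(rows) + 1L]] <- data.frame(
      name = paste("ECG", "Variability", .RR_FEATURES, sep = "_"),
      role = "ecg", group = "Variability", feature = names(.RR_FEATURES))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## Group of a feature name ("Zygomaticus_Similarity_Correlation" ->
## "Similarity"); NA for names not in Channel_Group_Feature form.
featureGroupOf <- function(names) {
  vapply(strsplit(names, "_", fixed = TRUE),
         function(p) if (length(p) >= 3L) p[2L] else NA_character_,
         character(1))
}

#' Mean baseline reference segments
#'
#' Element-wise mean of a subject's baseline (class B) windows, per waveform
#' channel; the reference the similarity features are computed against.
#'
#' @param ws a \linkS4class{LabeledWindowSet}.
#' @return named list (by role) of numeric vectors of window length.
#' @export
baselineReference <- function(ws) {
  bIdx <- which(ws@labels == "B")
  if (!length(bIdx)) stop("no baseline (B) windows available for subject ",
                          ws@subjectId)
  refs <- lapply(setdiff(names(ws@channels), "ecg"), function(role)
    rowMeans(ws@channels[[role]][, bIdx, drop = FALSE]))
  names(refs) <- setdiff(names(ws@channels), "ecg")
  refs
}

## Linear detrend (least-squares line removed).
.detrend <- function(x) {
  n <- length(x)
  t0 <- seq_len(n) - (n + 1) / 2
  x - mean(x) - sum(t0 * x) / sum(t0^2) * t0
}

## All 39 features of one waveform segment.
.waveformFeatures <- function(seg, ref, fs, cfg, detrendSpectral = FALSE) {
  segF <- if (detrendSpectral) .detrend(seg) else seg
  ent <- seg
  if (cfg@entropyDecim > 1L && length(seg) >= 8L * cfg@entropyDecim)
    ent <- decimateFFT(seg, cfg@entropyDecim)
  r <- cfg@rFrac * stats::sd(ent)
  c(amplitudeFeatures(seg),
    frequencyFeatures(segF, fs, cfPrinted = cfg@cfPrinted),
    stationarityFeatures(segF, fs, tiS = cfg@tiS, segLen = cfg@segLen,
                         overlap = cfg@overlap),
    aprox = approximateEntropy(ent, cfg@m, r),
    fuzzy = fuzzyEntropy(ent, cfg@m, r, cfg@fuzzyN),
    sample = sampleEntropy(ent, cfg@m, r),
    shannon = shannonEntropy(seg, cfg@bins),
    spectral = spectralEntropy(seg, fs),
    lagDependenceFeatures(seg, cfg@maxLag),
    variabilityFeatures(seg),
    coherenceFeatures(seg, ref, fs, segLen = cfg@segLen,
                      overlap = cfg@overlap),
    corr = similarityCorrelation(seg, ref),
    mutinfo = mutualInformation(seg, ref, cfg@bins))
}

#' Extract the feature vector of one window
#'
#' Computes the full feature set for window \code{j} of a window set: 39
#' features per waveform channel (similarity computed against the subject's
#' mean baseline segment) and the three RR features from the beats falling
#' inside the window. SCL is linearly detrended before the frequency and
#' stationarity groups.
#'
#' For a baseline window the similarity reference is the leave-one-out mean
#' of the other baseline windows, so a window is never compared against a
#' reference containing itself (a trivial self-match would otherwise inflate
#' the similarity of every baseline window).
#'
#' @param ws a \linkS4class{LabeledWindowSet}.
#' @param j window index.
#' @param baseRef baseline reference from [baselineReference()].
#' @param cfg a \linkS4class{FeatureConfig}.
#' @return named numeric vector (159 entries in the standard configuration).
#' @export
extractFeatureVector <- function(ws, j, baseRef = baselineReference(ws),
                                 cfg = featureConfig()) {
  tab <- painFeatureNames(intersect(.STANDARD_ROLES, names(ws@channels)))
  nB <- sum(ws@labels == "B")
  loo <- as.character(ws@labels[j]) == "B" && nB > 1L
  vals <- numeric(0)
  for (role in setdiff(unique(tab$role), "ecg")) {
    if (is.null(ws@channels[[role]]))
      stop("window set lacks channel with role ", role)
    seg <- ws@channels[[role]][, j]
    ref <- baseRef[[role]]
    if (loo) ref <- (nB * ref - seg) / (nB - 1L)
    vals <- c(vals, .waveformFeatures(seg, ref, ws@fs, cfg,
                                      detrendSpectral = role == "scl"))
  }
  if ("ecg" %in% tab$role) {
    rr <- new("RRSeries", beatTimes = ws@beatTimes,
              rrMs = if (length(ws@beatTimes) >= 2L)
                diff(ws@beatTimes) * 1000 else numeric(0))
    vals <- c(vals, rrFeatures(rr, ws@onsets[j], ws@onsets[j] + ws@windowS))
  }
  stats::setNames(vals, tab$name)
}

#' Extract the feature matrix of a window set
#'
#' Runs [extractFeatureVector()] over every window of a subject and returns
#' the features-by-windows matrix with subject and class annotation. Under
#' the standard five-channel configuration the result has exactly 159 rows,
#' with group sums 40 amplitude / 24 frequency / 24 stationarity / 20
#' entropy / 8 linearity / 19 variability / 24 similarity.
#'
#' @param ws a \linkS4class{LabeledWindowSet} (or a list of them, one per
#'   subject, which are extracted and combined).
#' @param cfg a \linkS4class{FeatureConfig}.
#' @return a \linkS4class{PainFeatureMatrix}.
#' @export
extractFeatures <- function(ws, cfg = featureConfig()) {
  if (is.list(ws)) {
    parts <- lapply(ws, extractFeatures, cfg = cfg)
    return(do.call(combineFeatureMatrices, parts))
  }
  stopifnot(is(ws, "LabeledWindowSet"))
  tab <- painFeatureNames(intersect(.STANDARD_ROLES, names(ws@channels)))
  baseRef <- baselineReference(ws)
  nw <- length(ws@labels)
  vals <- vapply(seq_len(nw),
                 function(j) extractFeatureVector(ws, j, baseRef, cfg),
                 numeric(nrow(tab)))
  rownames(vals) <- tab$name
  colnames(vals) <- sprintf("%s_w%03d", ws@subjectId, seq_len(nw))
  painFeatureMatrix(vals, rep(ws@subjectId, nw), as.character(ws@labels),
                    group = tab$group)
}

#' Combine feature matrices column-wise
#'
#' @param ... \linkS4class{PainFeatureMatrix} objects with identical feature
#'   rows.
#' @return a single \linkS4class{PainFeatureMatrix}.
#' @export
combineFeatureMatrices <- function(...) {
  parts <- list(...)
  x <- do.call(cbind, parts)
  new("PainFeatureMatrix", x)
}

#' Per-person z-normalization
#'
#' Standardizes every feature within every subject to mean 0 and standard
#' deviation 1. Features that are constant within a subject are set to 0
#' there and flagged in \code{rowData(x)$static} (they are removed later by
#' [pruneStatic()]).
#'
#' @param x a \linkS4class{PainFeatureMatrix}.
#' @return the normalized \linkS4class{PainFeatureMatrix}.
#' @export
znormPerPerson <- function(x) {
  stopifnot(is(x, "PainFeatureMatrix"))
  vals <- assay(x, "features")
  subj <- colData(x)$subject_id
  static <- rep(FALSE, nrow(vals))
  for (s in unique(subj)) {
    ix <- which(subj == s)
    v <- vals[, ix, drop = FALSE]
    mu <- rowMeans(v)
    sg <- apply(v, 1L, stats::sd)
    ## near-constant rows (sd at floating-point noise level relative to the
    ## mean) are numerically degenerate: flag them static rather than
    ## amplifying cancellation error
    zero <- !is.na(sg) & (sg == 0 | sg < abs(mu) * 1e-10)
    sg[zero] <- 1
    z <- (v - mu) / sg
    z[zero, ] <- 0
    vals[, ix] <- z
    static <- static | zero
  }
  assay(x, "features") <- vals
  rowData(x)$static <- static
  x
}
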
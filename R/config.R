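#' Simulator configuration
#'
#' Parameters of the synthetic protocol-structured dataset. The defaults
#' reproduce the study conditions of the heat-pain protocol: 85 subjects, four
#' stimulus levels applied 20 times each in randomized order (80 stimuli), 4 s
#' plateaus, pauses uniform on 8-12 s, 20 baseline windows per subject, 5.5 s
#' analysis windows, and monotone class-dependent physiological effects (EMG
#' burst gain, phasic SCL amplitude, RR shortening).
#'
#' @slot nSubjects integer(1), number of simulated subjects (default 85).
#' @slot repsPerLevel integer(1), stimuli per level (default 20).
#' @slot nBaseline integer(1), baseline windows per subject (default 20).
#' @slot plateauS numeric(1), stimulus plateau in s (default 4).
#' @slot pauseRange numeric(2), inter-stimulus pause bounds in s (default 8-12).
#' @slot windowS numeric(1), analysis window in s (default 5.5).
#' @slot fs numeric(1), sampling rate in Hz (default 512).
#' @slot emgBurstGain numeric(4), multiplicative EMG noise-scale gain per level
#'   during the stimulus window; monotone non-decreasing, >= 1.
#' @slot trapeziusAtten numeric(1) in (0, 1], fraction of the facial burst
#'   effect (gain - 1) retained by the trapezius channel.
#' @slot sclPhasicAmp numeric(4), phasic skin-conductance response amplitude
#'   per level in microsiemens; monotone non-decreasing.
#' @slot rrShortening numeric(4), reduction of the mean RR interval per level
#'   in ms during the stimulus window; monotone non-decreasing.
#' @slot trialSdLog numeric(1), sd (log scale) of the per-trial multiplicative
#'   variability of the EMG and SCL responses (default 0.9): individual
#'   stimuli often evoke little or no facial response, which is what makes
#'   the lower pain levels hard to classify.
#' @slot rrTrialSd numeric(1), per-trial additive sd of the RR shortening in
#'   ms (default 20).
#' @slot emgToneSdLog numeric(1), sd (log scale) of the slow (~30 s
#'   correlation time) multiplicative drift of resting muscle tone (default
#'   0.35); resting EMG amplitude is far from constant in real recordings,
#'   and this drift is what makes baseline and weak-stimulus windows overlap.
#' @slot emgSpontRate numeric(1), rate (per minute) of spontaneous EMG bursts
#'   unrelated to stimulation (default 3).
#' @slot emgSpontGain numeric(1), mean noise-scale gain of spontaneous bursts
#'   (default 2.2).
#' @slot sclSpontRate numeric(1), rate (per minute) of spontaneous skin
#'   conductance responses (default 2).
#' @slot sclSpontAmp numeric(1), mean amplitude of spontaneous SCRs in
#'   microsiemens (default 0.3).
#' @slot sclDriftSd numeric(1), sd of the slow stochastic tonic SCL drift in
#'   microsiemens (default 0.15).
#' @slot meanRR numeric(1), baseline mean RR in ms (default 850).
#' @slot sdnn numeric(1), RR standard deviation in ms (default 40).
#' @slot emgSigma numeric(1), median baseline EMG noise scale (default 8, a.u.).
#' @slot sclBase numeric(1), median tonic SCL (default 5 microsiemens).
#' @slot sclNoise numeric(1), SCL measurement noise sd (default 0.02).
#' @slot ecgNoise numeric(1), ECG additive noise sd relative to R peak
#'   (default 0.03).
#' @slot subjectScaleSd numeric(1), sd of the per-subject log-normal baseline
#'   scale (default 0.3), making per-person z-normalization non-trivial.
#' @slot seed integer(1), master RNG seed; per-subject substreams are derived
#'   from it so any subject is reproducible in isolation.
#'
#' @seealso [simConfig()], [generateDataset()]
#' @exportClass SimConfig
setClass("SimConfig",
  representation(nSubjects = "integer", repsPerLevel = "integer",
                 nBaseline = "integer", plateauS = "numeric",
                 pauseRange = "numeric", windowS = "numeric", fs = "numeric",
                 emgBurstGain = "numeric", trapeziusAtten = "numeric",
                 sclPhasicAmp = "numeric", rrShortening = "numeric",
                 trialSdLog = "numeric", rrTrialSd = "numeric",
                 emgToneSdLog = "numeric", emgSpontRate = "numeric", emgSpontGain = "numeric",
                 sclSpontRate = "numeric", sclSpontAmp = "numeric",
                 sclDriftSd = "numeric", meanRR = "numeric", sdnn = "numeric", emgSigma = "numeric",
                 sclBase = "numeric", sclNoise = "numeric", ecgNoise = "numeric",
                 subjectScaleSd = "numeric", seed = "integer"),
  prototype(nSubjects = 85L, repsPerLevel = 20L, nBaseline = 20L,
            plateauS = 4, pauseRange = c(8, 12), windowS = 5.5, fs = 512,
            emgBurstGain = c(T1 = 1.15, T2 = 1.5, T3 = 2.1, T4 = 2.8),
            trapeziusAtten = 0.5,
            sclPhasicAmp = c(T1 = 0.2, T2 = 0.6, T3 = 1.2, T4 = 2.0),
            rrShortening = c(T1 = 8, T2 = 20, T3 = 40, T4 = 60),
            trialSdLog = 0.9, rrTrialSd = 20,
            emgToneSdLog = 0.35, emgSpontRate = 3, emgSpontGain = 2.2,
            sclSpontRate = 2, sclSpontAmp = 0.3, sclDriftSd = 0.15,
            meanRR = 850, sdnn = 40, emgSigma = 8, sclBase = 5,
            sclNoise = 0.02, ecgNoise = 0.03, subjectScaleSd = 0.3,
            seed = 1L))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  if (object@repsPerLevel < 1L) msg <- c(msg, "repsPerLevel must be >= 1")
  if (object@nSubjects < 1L) msg <- c(msg, "nSubjects must be >= 1")
  mono <- function(v) all(diff(v) >= 0)
  if (length(object@emgBurstGain) != 4L || !mono(object@emgBurstGain) ||
      any(object@emgBurstGain < 1))
    msg <- c(msg, "emgBurstGain must be 4 monotone non-decreasing values >= 1")
  if (length(object@sclPhasicAmp) != 4L || !mono(object@sclPhasicAmp))
    msg <- c(msg, "sclPhasicAmp must be 4 monotone non-decreasing values")
  if (length(object@rrShortening) != 4L || !mono(object@rrShortening))
    msg <- c(msg, "rrShortening must be 4 monotone non-decreasing values")
  if (object@fs <= 0) msg <- c(msg, "fs must be > 0")
  if (length(msg)) msg else TRUE
})

#' Build a simulator configuration
#'
#' @param ... named slots overriding the defaults of
#'   \linkS4class{SimConfig} (e.g. \code{nSubjects = 10, seed = 7}).
#' @return A validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(nSubjects = 2, seed = 1)
#' @export
simConfig <- function(...) {
  args <- list(...)
  for (nm in intersect(names(args), c("nSubjects", "repsPerLevel",
                                      "nBaseline", "seed")))
    args[[nm]] <- as.integer(args[[nm]])
  for (nm in intersect(names(args), c("emgBurstGain", "sclPhasicAmp",
                                      "rrShortening")))
    args[[nm]] <- stats::setNames(as.numeric(args[[nm]]),
                                  c("T1", "T2", "T3", "T4"))
  do.call(new, c(list(Class = "SimConfig"), args))
}

#' Feature-extraction configuration
#'
#' Tunable parameters of the 159-feature extraction. Defaults follow common
#' practice in the biosignal literature: template entropies with m = 2 and
#' tolerance r = 0.2 sd, fuzzy exponent 2, 16 histogram bins, 256-sample
#' spectral segments with 50% overlap, 0.5 s stationarity subsegments and a
#' maximum lag of 10 for the lag-dependence features.
#'
#' @slot m integer(1), template length for ApEn/SampEn/FuzzyEn.
#' @slot rFrac numeric(1), entropy tolerance as a fraction of the segment sd.
#' @slot fuzzyN numeric(1), exponent of the fuzzy membership function.
#' @slot bins integer(1), histogram bins for Shannon entropy and mutual
#'   information.
#' @slot segLen integer(1), samples per spectral segment (Welch/spectrogram).
#' @slot overlap numeric(1) in [0, 1), fractional segment overlap.
#' @slot tiS numeric(1), subsegment length (s) for the stationarity me/sd
#'   features.
#' @slot maxLag integer(1), maximum lag K of the lag-dependence features.
#' @slot entropyDecim integer(1), decimation factor applied to a segment
#'   before the template entropies (1 = none).
#' @slot cfPrinted logical(1), if TRUE use the printed central-frequency
#'   variant (fh - fl)/2 instead of the textual (fh + fl)/2.
#'
#' @seealso [featureConfig()], [extractFeatures()]
#' @exportClass FeatureConfig
setClass("FeatureConfig",
  representation(m = "integer", rFrac = "numeric", fuzzyN = "numeric",
                 bins = "integer", segLen = "integer", overlap = "numeric",
                 tiS = "numeric", maxLag = "integer", entropyDecim = "integer",
                 cfPrinted = "logical"),
  prototype(m = 2L, rFrac = 0.2, fuzzyN = 2, bins = 16L, segLen = 256L,
            overlap = 0.5, tiS = 0.5, maxLag = 10L, entropyDecim = 4L,
            cfPrinted = FALSE))

#' Build a feature-extraction configuration
#' @param ... named slots overriding \linkS4class{FeatureConfig} defaults.
#' @return A \linkS4class{FeatureConfig}.
#' @export
featureConfig <- function(...) {
  args <- list(...)
  for (nm in intersect(names(args), c("m", "bins", "segLen", "maxLag",
                                      "entropyDecim")))
    args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c(list(Class = "FeatureConfig"), args))
}

#' RBF-SVM grid-search configuration
#'
#' Exponentially growing hyperparameter grids, C = 2^-5, 2^-3, ..., 2^15 and
#' gamma = 2^-15, 2^-13, ..., 2^3, scored by 3-fold cross-validated accuracy.
#'
#' @slot cGrid numeric, candidate misclassification costs.
#' @slot gammaGrid numeric, candidate kernel radii.
#' @slot cvFolds integer(1), cross-validation folds (default 3).
#'
#' @seealso [svmConfig()], [gridSearchTrain()]
#' @exportClass SVMConfig
setClass("SVMConfig",
  representation(cGrid = "numeric", gammaGrid = "numeric", cvFolds = "integer"),
  prototype(cGrid = 2^seq(-5, 15, by = 2), gammaGrid = 2^seq(-15, 3, by = 2),
            cvFolds = 3L))

setValidity("SVMConfig", function(object) {
  if (object@cvFolds < 2L) "cvFolds must be >= 2" else TRUE
})

#' Build an SVM grid-search configuration
#' @param ... named slots overriding \linkS4class{SVMConfig} defaults.
#' @return An \linkS4class{SVMConfig}.
#' @export
svmConfig <- function(...) {
  args <- list(...)
  if ("cvFolds" %in% names(args)) args$cvFolds <- as.integer(args$cvFolds)
  do.call(new, c(list(Class = "SVMConfig"), args))
}

#' Train/test split specification
#'
#' Stratified random split of labelled windows into training and test sets,
#' 75/25 by default (8500 windows from 85 subjects split into 6375 training
#' and 2125 test vectors).
#'
#' @slot trainFraction numeric(1) in (0, 1).
#' @slot seed integer(1), RNG seed of the split.
#' @slot groupBySubject logical(1), if TRUE all windows of a subject fall on
#'   the same side of the split (default FALSE: window-level stratification).
#'
#' @seealso [splitSpec()], [splitData()]
#' @exportClass SplitSpec
setClass("SplitSpec",
  representation(trainFraction = "numeric", seed = "integer",
                 groupBySubject = "logical"),
  prototype(trainFraction = 0.75, seed = 1L, groupBySubject = FALSE))

#' Build a split specification
#' @param ... named slots overriding \linkS4class{SplitSpec} defaults.
#' @return A \linkS4class{SplitSpec}.
#' @export
splitSpec <- function(...) {
  args <- list(...)
  if ("seed" %in% names(args)) args$seed <- as.integer(args$seed)
  do.call(new, c(list(Class = "SplitSpec"), args))
}
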
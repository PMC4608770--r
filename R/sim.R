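## Total duration (s) implied by a schedule: last activity + 10 s tail.
recordingDuration <- function(schedule, windowS = 5.5) {
  ev <- schedule@events
  last <- max(0, if (nrow(ev)) max(ev$onset_s + ev$plateau_s) else 0,
              if (length(schedule@baselineOnsets))
                max(schedule@baselineOnsets + windowS) else 0)
  last + 10
}

#' Generate a randomized stimulus schedule
#'
#' Emulates the phasic heat protocol: each of the four levels applied
#' \code{repsPerLevel} times in randomized order with 4 s plateaus and
#' pauses drawn i.i.d. uniform from \code{pauseRange}; baseline ("non-pain")
#' windows are placed inside pauses, at least 1.5 s after the preceding
#' plateau ends and clear of the next onset.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @param seed optional integer seed; if NULL the current RNG stream is used.
#' @return A \linkS4class{StimulusSchedule}.
#' @examples
#' sched <- generateSchedule(simConfig(), seed = 1)
#' table(stimulusEvents(sched)$level)
#' @export
generateSchedule <- function(cfg = simConfig(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lev <- rep(c("T1", "T2", "T3", "T4"), each = cfg@repsPerLevel)
  lev <- lev[sample.int(length(lev))]
  nEv <- length(lev)
  pauses <- stats::runif(nEv, cfg@pauseRange[1], cfg@pauseRange[2])
  onsets <- 10 + c(0, cumsum(cfg@plateauS + pauses[-nEv]))
  nB <- cfg@nBaseline
  if (nB > nEv) {
    warning("nBaseline capped at the number of inter-stimulus pauses (", nEv, ")")
    nB <- nEv
  }
  bIdx <- if (nB > 0) unique(round(seq(1, nEv, length.out = nB))) else integer(0)
  ends <- onsets + cfg@plateauS
  bOn <- ends[bIdx] + pmax(1.5, (pauses[bIdx] - cfg@windowS) / 2)
  stimulusSchedule(data.frame(level = lev, onset_s = onsets,
                              plateau_s = cfg@plateauS),
                   baselineOnsets = bOn, pauseRange = cfg@pauseRange)
}

## Raised-cosine gain envelope over the recording for one channel: 1 outside
## stimuli, `gain` inside [onset+lat, onset+plateau], 0.3 s cosine ramps.
.burstEnvelope <- function(n, fs, events, gains, ramp = 0.3, latency = 0.2) {
  env <- rep(1, n)
  for (i in seq_along(gains)) {
    g <- gains[i]
    if (g == 1) next
    a <- events$onset_s[i] + latency
    b <- events$onset_s[i] + events$plateau_s[i]
    ix <- max(1L, floor((a - ramp) * fs) + 1L):min(n, ceiling((b + ramp) * fs) + 1L)
    if (ix[1L] > n) next
    ti <- (ix - 1L) / fs
    w <- rep(1, length(ix))
    up <- ti < a
    w[up] <- 0.5 - 0.5 * cos(pi * (ti[up] - (a - ramp)) / ramp)
    dn <- ti > b
    w[dn] <- 0.5 + 0.5 * cos(pi * (ti[dn] - b) / ramp)
    env[ix] <- pmax(env[ix], 1 + (g - 1) * w)
  }
  env
}

#' Synthesize a surface-EMG channel
#'
#' Zero-mean band-limited (20-250 Hz) Gaussian noise at baseline scale
#' \code{sigma0}; during each stimulus the noise scale is multiplied by the
#' level's burst gain with smooth cosine on/off ramps (muscle tone rising with
#' stimulus intensity). Trapezius retains only a fraction
#' \code{trapeziusAtten} of the facial effect.
#'
#' @param schedule a \linkS4class{StimulusSchedule}.
#' @param role one of "emg_zyg", "emg_cor", "emg_tra".
#' @param cfg a \linkS4class{SimConfig}.
#' @param seed optional integer seed.
#' @param sigma0 baseline noise scale; defaults to \code{cfg@emgSigma}.
#' @param nSamples total samples; defaults to the schedule's duration.
#' @return numeric vector of samples.
#' @export
synthEMG <- function(schedule, role = "emg_zyg", cfg = simConfig(),
                     seed = NULL, sigma0 = cfg@emgSigma, nSamples = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fs <- cfg@fs
  if (is.null(nSamples))
    nSamples <- ceiling(recordingDuration(schedule, cfg@windowS) * fs)
  x <- stats::rnorm(nSamples)
  ## band-limit by the zero-phase Butterworth response; the wrap-around of
  ## circular filtering is harmless on stationary noise
  hi <- min(250, 0.99 * fs / 2)
  x <- .fftApplyMag(x, function(f) {
    hp <- ifelse(f > 0, 1 / (1 + (20 / pmax(f, 1e-12))^8), 0)
    hp / (1 + (f / hi)^8)
  }, fs, circular = TRUE)
  x <- x / stats::sd(x) * sigma0
  ev <- schedule@events
  if (nrow(ev)) {
    atten <- if (role == "emg_tra") cfg@trapeziusAtten else 1
    ## per-trial response variability: mean-1 log-normal on the burst effect,
    ## so many individual stimuli evoke little or no muscle response
    trial <- stats::rlnorm(nrow(ev), -cfg@trialSdLog^2 / 2, cfg@trialSdLog)
    g <- 1 + (cfg@emgBurstGain[ev$level] - 1) * atten * trial
    x <- x * .burstEnvelope(nSamples, fs, ev, g)
  }
  ## slow multiplicative drift of resting muscle tone (~30 s correlation)
  if (cfg@emgToneSdLog > 0) {
    g <- stats::rnorm(nSamples)
    g <- .fftApplyMag(g, function(f) 1 / (1 + (f / 0.0075)^4), fs,
                      circular = TRUE)
    x <- x * exp(cfg@emgToneSdLog * g / stats::sd(g))
  }
  ## spontaneous bursts unrelated to stimulation
  if (cfg@emgSpontRate > 0) {
    durS <- nSamples / fs
    nSp <- stats::rpois(1, cfg@emgSpontRate * durS / 60)
    if (nSp > 0) {
      sp <- data.frame(onset_s = stats::runif(nSp, 0, durS),
                       plateau_s = stats::rlnorm(nSp, log(0.8), 0.5))
      gSp <- 1 + (cfg@emgSpontGain - 1) * stats::rlnorm(nSp, 0, 0.5)
      x <- x * .burstEnvelope(nSamples, fs, sp, gSp, latency = 0)
    }
  }
  x
}

#' Synthesize a skin-conductance (SCL) channel
#'
#' Slow tonic level with drift plus, for each stimulus, a phasic skin
#' conductance response: onset latency uniform on 1-3 s, amplitude set by the
#' level, and a smooth exponential rise/decay kernel (rise tau 0.7 s, decay
#' tau 3 s, unit peak), plus small measurement noise.
#'
#' @inheritParams synthEMG
#' @param tonic baseline conductance in microsiemens; default
#'   \code{cfg@sclBase}.
#' @return numeric vector of samples (microsiemens).
#' @export
synthSCL <- function(schedule, cfg = simConfig(), seed = NULL,
                     tonic = cfg@sclBase, nSamples = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fs <- cfg@fs
  if (is.null(nSamples))
    nSamples <- ceiling(recordingDuration(schedule, cfg@windowS) * fs)
  ## tonic level with stochastic slow drift (~0.03 Hz low-passed noise)
  drift <- stats::rnorm(nSamples)
  drift <- .fftApplyMag(drift, function(f) 1 / (1 + (f / 0.03)^8), fs,
                        circular = TRUE)
  x <- tonic + cfg@sclDriftSd * drift / stats::sd(drift)
  ev <- schedule@events
  taur <- 0.7
  addSCR <- function(x, t0, a, taud = 3.0) {
    i0 <- floor(t0 * fs) + 1L
    if (i0 > nSamples || a == 0) return(x)
    tpk <- taur * log((taur + taud) / taur)
    peak <- (1 - exp(-tpk / taur)) * exp(-tpk / taud)
    i1 <- min(nSamples, i0 + as.integer(20 * fs))
    tt <- (seq.int(i0, i1) - 1L) / fs - t0
    x[i0:i1] <- x[i0:i1] + a / peak * (1 - exp(-tt / taur)) * exp(-tt / taud)
    x
  }
  if (nrow(ev)) {
    lat <- stats::runif(nrow(ev), 1, 3)
    amp <- cfg@sclPhasicAmp[ev$level] *
      stats::rlnorm(nrow(ev), -cfg@trialSdLog^2 / 2, cfg@trialSdLog)
    taud <- 3 * stats::rlnorm(nrow(ev), 0, 0.3)
    for (i in seq_len(nrow(ev)))
      x <- addSCR(x, ev$onset_s[i] + lat[i], amp[i], taud[i])
  }
  ## spontaneous (non-specific) skin conductance responses
  if (cfg@sclSpontRate > 0) {
    durS <- nSamples / fs
    nSp <- stats::rpois(1, cfg@sclSpontRate * durS / 60)
    for (i in seq_len(nSp))
      x <- addSCR(x, stats::runif(1, 0, durS),
                  cfg@sclSpontAmp * stats::rlnorm(1, 0, 0.5),
                  3 * stats::rlnorm(1, 0, 0.3))
  }
  if (cfg@sclNoise > 0) x <- x + stats::rnorm(nSamples, 0, cfg@sclNoise)
  x
}

#' Synthesize an ECG channel
#'
#' A biphasic QRS-like template train. Interbeat intervals follow an AR(1)
#' process around the mean RR with standard deviation \code{sdnn} (giving the
#' successive-difference structure RMSSD measures); while a stimulus window is
#' active the mean RR is reduced by the level's shortening.
#'
#' @inheritParams synthEMG
#' @param meanRR mean interbeat interval in ms; default \code{cfg@meanRR}.
#' @param sdnn RR standard deviation in ms; default \code{cfg@sdnn}.
#' @return numeric vector of samples (mV-scale arbitrary units).
#' @export
synthECG <- function(schedule, cfg = simConfig(), seed = NULL,
                     meanRR = cfg@meanRR, sdnn = cfg@sdnn, nSamples = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fs <- cfg@fs
  if (is.null(nSamples))
    nSamples <- ceiling(recordingDuration(schedule, cfg@windowS) * fs)
  dur <- nSamples / fs
  ev <- schedule@events
  evOn <- ev$onset_s
  evShort <- if (nrow(ev))
    pmax(0, cfg@rrShortening[ev$level] +
           stats::rnorm(nrow(ev), 0, cfg@rrTrialSd)) else numeric(0)
  shorten <- function(tm) {
    if (!nrow(ev)) return(0)
    i <- findInterval(tm, evOn)
    if (i >= 1L && tm < evOn[i] + cfg@windowS) evShort[i] else 0
  }
  phi <- 0.4
  beats <- numeric(0)
  tcur <- 0.5
  dev <- 0
  while (tcur < dur) {
    beats <- c(beats, tcur)
    if (sdnn > 0)
      dev <- phi * dev + stats::rnorm(1, 0, sdnn * sqrt(1 - phi^2))
    rr <- meanRR + dev - shorten(tcur)
    rr <- max(rr, 250)
    tcur <- tcur + rr / 1000
  }
  ## biphasic QRS template (Ricker wavelet, sigma 10 ms)
  sg <- 0.010
  tt <- seq(-0.04, 0.04, by = 1 / fs)
  tpl <- (1 - (tt / sg)^2) * exp(-tt^2 / (2 * sg^2))
  x <- numeric(nSamples)
  for (b in beats) {
    i0 <- round(b * fs) + 1L
    ix <- i0 + seq_along(tpl) - 1L - (length(tpl) %/% 2)
    ok <- ix >= 1L & ix <= nSamples
    x[ix[ok]] <- x[ix[ok]] + tpl[ok]
  }
  if (cfg@ecgNoise > 0) x <- x + stats::rnorm(nSamples, 0, cfg@ecgNoise)
  x
}

#' Simulate one subject
#'
#' Draws a subject-specific RNG substream from the master seed, generates a
#' randomized schedule and the five standard channels (per-subject log-normal
#' baseline scales make per-person normalization non-trivial).
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @param subjectIndex integer(1), 1-based subject number.
#' @return list with elements \code{recording}
#'   (\linkS4class{BioRecording}) and \code{schedule}
#'   (\linkS4class{StimulusSchedule}).
#' @export
simulateSubject <- function(cfg = simConfig(), subjectIndex = 1L) {
  set.seed(deriveSeed(cfg@seed, "subject", subjectIndex))
  schedule <- generateSchedule(cfg)
  ## round up to a fast composite FFT length
  n <- stats::nextn(ceiling(recordingDuration(schedule, cfg@windowS) * cfg@fs),
                    c(2L, 3L, 5L))
  scl <- stats::rlnorm(5, 0, cfg@subjectScaleSd)  # per-channel subject scales
  rrSubj <- cfg@meanRR * stats::rlnorm(1, 0, 0.05)
  channels <- list(
    emg_zyg = synthEMG(schedule, "emg_zyg", cfg, sigma0 = cfg@emgSigma * scl[1],
                       nSamples = n),
    emg_cor = synthEMG(schedule, "emg_cor", cfg, sigma0 = cfg@emgSigma * scl[2],
                       nSamples = n),
    emg_tra = synthEMG(schedule, "emg_tra", cfg, sigma0 = cfg@emgSigma * scl[3],
                       nSamples = n),
    scl = synthSCL(schedule, cfg, tonic = cfg@sclBase * scl[4], nSamples = n),
    ecg = synthECG(schedule, cfg, meanRR = rrSubj, nSamples = n))
  rec <- bioRecording(sprintf("S%03d", subjectIndex), cfg@fs, channels)
  list(recording = rec, schedule = schedule)
}

#' Generate a full synthetic dataset
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @return list of length \code{cfg@nSubjects}; each element as returned by
#'   [simulateSubject()]. Identical configs (including seed) give bit-identical
#'   output.
#' @examples
#' ds <- generateDataset(simConfig(nSubjects = 2, repsPerLevel = 2,
#'                                 nBaseline = 2, seed = 1))
#' length(ds)
#' @export
generateDataset <- function(cfg = simConfig()) {
  lapply(seq_len(cfg@nSubjects), function(i) simulateSubject(cfg, i))
}
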
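#' Interbeat-interval series
#'
#' Beat times (s) from QRS detection and the derived RR intervals (ms).
#'
#' @slot beatTimes numeric, beat times in seconds.
#' @slot rrMs numeric, interbeat intervals in ms;
#'   \code{length(rrMs) == length(beatTimes) - 1} (both empty when fewer than
#'   two beats were found).
#' @seealso [detectRR()], [rrFeatures()]
#' @exportClass RRSeries
setClass("RRSeries", representation(beatTimes = "numeric", rrMs = "numeric"))

setValidity("RRSeries", function(object) {
  if (length(object@beatTimes) >= 2L &&
      length(object@rrMs) != length(object@beatTimes) - 1L)
    return("rrMs must have one element less than beatTimes")
  if (any(object@rrMs <= 0)) return("rr intervals must be positive")
  TRUE
})

setMethod("show", "RRSeries", function(object) {
  cat("RRSeries |", length(object@beatTimes), "beats")
  if (length(object@rrMs))
    cat(" | mean RR", sprintf("%.1f ms", mean(object@rrMs)))
  cat("\n")
})

## Apply a real, even magnitude response to x by FFT, with mirror padding to
## a fast composite length to suppress wrap-around transients. circular=TRUE
## skips the padding (appropriate for stationary noise synthesis, where the
## circular wrap-around is itself stationary).
.fftApplyMag <- function(x, mag2fun, fs, circular = FALSE) {
  n <- length(x)
  if (circular) {
    m <- n
    xp <- x
  } else {
    m <- stats::nextn(2L * n, c(2L, 3L, 5L))
    ext <- m - n
    refl <- rev(x)
    tailpad <- if (ext <= n) refl[seq_len(ext)] else c(refl, x)[seq_len(ext)]
    xp <- c(x, tailpad)
  }
  k <- seq_len(m) - 1L
  f <- pmin(k, m - k) * fs / m
  H2 <- mag2fun(f)
  Re(stats::fft(stats::fft(xp) * H2, inverse = TRUE))[seq_len(n)] / m
}

#' Zero-phase Butterworth band-pass filter
#'
#' Band-pass filtering with the forward-backward (zero-phase) response of a
#' cascade of an order-\code{order} Butterworth high-pass at \code{lo} and
#' low-pass at \code{hi}. The squared magnitude response of the cascade is
#' applied in the frequency domain (with mirror padding), which is the exact
#' zero-phase forward-backward response without start-up transients and is
#' numerically stable even for very wide bands such as the 0.1-250 Hz ECG
#' band. When \code{fs <= 2 * hi} the upper edge is clipped to 0.99 of the
#' Nyquist frequency with a warning.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param lo,hi band edges in Hz, 0 < lo < hi.
#' @param order Butterworth order of each section (default 4).
#' @return filtered vector, same length as \code{x}.
#' @examples
#' x <- sin(2 * pi * 5 * seq(0, 2, by = 1/512))
#' y <- butterworthBandpass(x, 512, 20, 250)   # 5 Hz is strongly attenuated
#' @export
butterworthBandpass <- function(x, fs, lo, hi, order = 4) {
  nyq <- fs / 2
  if (!(lo > 0 && hi > lo)) stop("band edges must satisfy 0 < lo < hi")
  if (hi >= nyq) {
    warning("upper band edge clipped to 0.99 * Nyquist (", 0.99 * nyq, " Hz)")
    hi <- 0.99 * nyq
    if (hi <= lo) stop("band collapsed after Nyquist clipping")
  }
  if (!length(x) || all(x == 0)) return(x)
  .fftApplyMag(x, function(f) {
    hp <- ifelse(f > 0, 1 / (1 + (lo / pmax(f, 1e-12))^(2 * order)), 0)
    lp <- 1 / (1 + (f / hi)^(2 * order))
    hp * lp
  }, fs)
}

#' Empirical-mode-decomposition denoising
#'
#' Decomposes the signal into intrinsic mode functions (IMFs) by sifting with
#' natural-cubic-spline envelopes, then reconstructs it without the leading
#' IMFs whose energy is statistically consistent with broadband noise. An IMF
#' k is treated as noise while (a) its energy does not exceed the white-noise
#' energy model E1 / beta^(k-1) (beta = 2.01, anchored on a robust estimate of
#' the IMF-1 noise energy) by more than a factor \code{tau}, and (b) it is
#' spectrally flat (normalised spectral entropy >= 0.5) - the guard that keeps
#' a narrowband, noise-free first IMF intact.
#'
#' @param x numeric vector of length >= 64.
#' @param fs sampling rate in Hz.
#' @param tau energy-consistency tolerance factor (default 2).
#' @return denoised vector, same length. If the decomposition yields no IMFs
#'   (e.g. constant input) the signal is returned unchanged; on decomposition
#'   failure the input is passed through with a warning.
#' @export
emdDenoise <- function(x, fs, tau = 2) {
  if (length(x) < 64) stop("emdDenoise requires at least 64 samples")
  dec <- tryCatch(emdC(as.numeric(x), 6L, 10L, 0.05),
                  error = function(e) NULL)
  if (is.null(dec)) {
    warning("EMD decomposition failed; signal passed through")
    return(x)
  }
  imfs <- dec$imfs
  if (is.null(imfs) || ncol(imfs) == 0L) return(x)
  K <- ncol(imfs)
  energy <- colSums(imfs^2)
  sigma1 <- stats::median(abs(imfs[, 1L])) / 0.6745
  e1hat <- length(x) * sigma1^2
  beta <- 2.01
  jstar <- 0L
  for (k in seq_len(K)) {
    model <- e1hat / beta^(k - 1)
    flat <- spectralEntropy(imfs[, k], fs)
    noisy <- is.finite(flat) && flat >= 0.5 && energy[k] <= tau * model
    if (!noisy) break
    jstar <- k
  }
  if (jstar == 0L) return(x)
  keep <- if (jstar < K) rowSums(imfs[, (jstar + 1L):K, drop = FALSE]) else 0
  as.numeric(keep + dec$residue)
}

#' Hilbert-envelope EMG burst detection
#'
#' Computes the analytic-signal envelope of a band-passed EMG trace, smooths
#' it with a short moving average, and marks as bursts the intervals where the
#' envelope exceeds a robust baseline level (median + k * MAD) for at least
#' \code{minDur} seconds.
#'
#' @param x band-passed EMG samples.
#' @param fs sampling rate in Hz.
#' @param k threshold in baseline scale units (default 3.5).
#' @param minDur minimum burst duration in seconds (default 0.1).
#' @param smoothS moving-average width in seconds (default 0.05).
#' @return data.frame with columns \code{onset_s}, \code{offset_s}
#'   (possibly zero rows), ordered and non-overlapping.
#' @export
detectBurstsHilbert <- function(x, fs, k = 3.5, minDur = 0.1, smoothS = 0.05) {
  if (!length(x) || all(x == 0))
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0)))
  env <- Mod(analyticSignal(x))
  env <- movAvg(env, max(1L, as.integer(round(smoothS * fs))))
  mu <- stats::median(env)
  sg <- stats::mad(env)
  thr <- mu + k * sg
  above <- env > thr
  runs <- logicalRuns(above)
  if (nrow(runs)) {
    keep <- (runs$end - runs$start + 1L) >= minDur * fs
    runs <- runs[keep, , drop = FALSE]
  }
  data.frame(onset_s = (runs$start - 1L) / fs, offset_s = runs$end / fs)
}

#' Cut labelled pain / non-pain windows
#'
#' Cuts one fixed-length window per stimulus (the "pain window", anchored at
#' stimulus onset, spanning the 4 s plateau plus the tail of the response) and
#' one per baseline onset (the "non-pain window", class B). Under the
#' standard protocol this yields 100 windows per subject: 20 each of B,
#' T1..T4. Windows that would run past the end of the recording are dropped
#' with a warning.
#'
#' @param recording a \linkS4class{BioRecording}.
#' @param schedule a \linkS4class{StimulusSchedule}.
#' @param windowS window length in seconds (default 5.5).
#' @param beatTimes optional beat times (s) carried into the result for RR
#'   features.
#' @return a \linkS4class{LabeledWindowSet}; channels are stored by role.
#' @export
cutWindows <- function(recording, schedule, windowS = 5.5,
                       beatTimes = numeric(0)) {
  fs <- recording@fs
  nSeg <- as.integer(round(windowS * fs))
  N <- nSamples(recording)
  ev <- schedule@events
  onsets <- c(ev$onset_s, schedule@baselineOnsets)
  labels <- c(ev$level, rep("B", length(schedule@baselineOnsets)))
  o <- order(onsets)
  onsets <- onsets[o]; labels <- labels[o]
  i0 <- floor(onsets * fs) + 1L
  ok <- i0 >= 1L & (i0 + nSeg - 1L) <= N
  if (any(!ok))
    warning(sum(!ok), " window(s) exceed the recording and were dropped")
  i0 <- i0[ok]; onsets <- onsets[ok]; labels <- labels[ok]
  roles <- recording@channelRole
  channels <- lapply(names(roles), function(nm) {
    sig <- recording@channels[[nm]]
    vapply(i0, function(s) sig[s:(s + nSeg - 1L)], numeric(nSeg))
  })
  names(channels) <- unname(roles[names(roles)])
  new("LabeledWindowSet", subjectId = recording@subjectId, fs = fs,
      windowS = windowS,
      labels = factor(labels, levels = .CLASS_LEVELS),
      onsets = onsets, channels = channels, beatTimes = as.numeric(beatTimes))
}

#' QRS detection and RR series
#'
#' Derivative-energy peak picking on a filtered ECG trace: the squared first
#' difference is smoothed (80 ms moving average), candidate beats are runs
#' above an adaptive threshold, and beats closer than the 250 ms refractory
#' period are merged keeping the stronger one.
#'
#' @param x filtered ECG samples (0.1-250 Hz band).
#' @param fs sampling rate in Hz.
#' @param refractory refractory period in seconds (default 0.25).
#' @return an \linkS4class{RRSeries}; empty when fewer than two beats are
#'   found (downstream RR features then carry the degenerate-value sentinel).
#' @export
detectRR <- function(x, fs, refractory = 0.25) {
  emptyRR <- new("RRSeries", beatTimes = numeric(0), rrMs = numeric(0))
  if (length(x) < 3L) return(emptyRR)
  e <- c(0, diff(x))^2
  s <- movAvg(e, max(1L, as.integer(round(0.08 * fs))))
  top <- stats::quantile(s, 0.999, names = FALSE)
  if (top <= 0) return(emptyRR)
  thr <- 0.3 * top
  runs <- logicalRuns(s > thr)
  if (!nrow(runs)) return(emptyRR)
  peaks <- vapply(seq_len(nrow(runs)), function(i) {
    seg <- runs$start[i]:runs$end[i]
    seg[which.max(s[seg])]
  }, integer(1))
  amp <- s[peaks]
  ## enforce refractory period, keep the stronger of two close peaks
  keep <- logical(length(peaks))
  last <- -Inf; lastIdx <- 0L
  for (i in seq_along(peaks)) {
    if ((peaks[i] - last) / fs >= refractory) {
      keep[i] <- TRUE; last <- peaks[i]; lastIdx <- i
    } else if (amp[i] > amp[lastIdx]) {
      keep[lastIdx] <- FALSE; keep[i] <- TRUE; last <- peaks[i]; lastIdx <- i
    }
  }
  beats <- (peaks[keep] - 1L) / fs
  if (length(beats) < 2L) return(emptyRR)
  new("RRSeries", beatTimes = beats, rrMs = diff(beats) * 1000)
}

#' Preprocess one recording into labelled windows
#'
#' Runs the standard preprocessing chain: Butterworth band-pass of the EMG
#' channels (20-250 Hz) and the ECG (0.1-250 Hz, upper edge clipped below
#' Nyquist when needed), QRS/RR detection on the filtered ECG, cutting of
#' 5.5 s pain / non-pain windows, and EMD denoising of each EMG window
#' segment. SCL is not band-pass filtered; it is detrended per window at
#' feature-extraction time.
#'
#' @param recording a \linkS4class{BioRecording}.
#' @param schedule a \linkS4class{StimulusSchedule}.
#' @param windowS window length in seconds (default 5.5).
#' @param emd logical, apply EMD denoising to EMG segments (default TRUE).
#' @return a \linkS4class{LabeledWindowSet} carrying the detected beat times.
#' @export
preprocessRecording <- function(recording, schedule, windowS = 5.5,
                                emd = TRUE) {
  fs <- recording@fs
  roles <- recording@channelRole
  chans <- recording@channels
  for (nm in names(roles)) {
    if (roles[[nm]] == "ecg")
      chans[[nm]] <- suppressWarnings(
        butterworthBandpass(chans[[nm]], fs, 0.1, 250))
  }
  filt <- bioRecording(recording@subjectId, fs, chans, roles)
  rr <- detectRR(channelSignal(filt, "ecg"), fs)
  ws <- cutWindows(filt, schedule, windowS, beatTimes = rr@beatTimes)
  ## EMG band-pass applied per segment (zero-phase, mirror-padded), then EMD
  for (role in intersect(names(ws@channels),
                         c("emg_zyg", "emg_cor", "emg_tra"))) {
    m <- ws@channels[[role]]
    for (j in seq_len(ncol(m))) {
      m[, j] <- butterworthBandpass(m[, j], fs, 20, 250)
      if (emd) m[, j] <- emdDenoise(m[, j], fs)
    }
    ws@channels[[role]] <- m
  }
  ws
}
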
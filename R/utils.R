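## Sentinel for degenerate feature values: a flagged missing value. Columns
## (features) containing it are removed by pruneStatic().
.SENTINEL <- NA_real_

#' Derive a reproducible sub-seed
#'
#' Fans a master seed out into independent substreams (per stage, per subject)
#' with a deterministic integer hash, so that any subject or stage can be
#' regenerated in isolation. Results stay below 2^31.
#'
#' @param seed integer(1), master seed.
#' @param ... further integers or strings tagging the substream.
#' @return integer(1) in [0, 2^31 - 1].
#' @examples
#' deriveSeed(1, "subject", 12)
#' @export
deriveSeed <- function(seed, ...) {
  tags <- list(...)
  h <- as.double(seed) %% 2147483647
  for (t in tags) {
    if (is.character(t)) t <- sum(utf8ToInt(paste(t, collapse = ""))) else t <- as.double(t)
    ## 31-bit multiplicative mix (Park-Miller constants)
    h <- (h * 48271 + t * 16807 + 12345) %% 2147483647
  }
  as.integer(h)
}

## Analytic signal via FFT: x + i * H(x). Returns complex vector.
analyticSignal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

## Welch averaged modified periodograms (Hann taper). With y supplied, also
## returns the cross-spectrum. frames = matrix of per-frame auto-spectra of x
## (frequency x time), used as the spectrogram for the stationarity features.
welchSpectra <- function(x, y = NULL, fs, segLen = 256L, overlap = 0.5) {
  n <- length(x)
  segLen <- min(segLen, n)
  step <- max(1L, as.integer(round(segLen * (1 - overlap))))
  starts <- seq.int(1L, n - segLen + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(segLen) / (segLen + 1))
  idx <- outer(seq_len(segLen) - 1L, starts, "+")
  Xf <- stats::mvfft(matrix(x[idx], nrow = segLen) * w)
  nb <- segLen %/% 2 + 1L
  Xf <- Xf[seq_len(nb), , drop = FALSE]
  Pxx <- Re(Xf * Conj(Xf))
  out <- list(f = (seq_len(nb) - 1L) * fs / segLen,
              Sxx = rowMeans(Pxx), frames = Pxx, nFrames = length(starts))
  if (!is.null(y)) {
    Yf <- stats::mvfft(matrix(y[idx], nrow = segLen) * w)[seq_len(nb), , drop = FALSE]
    out$Syy <- rowMeans(Re(Yf * Conj(Yf)))
    out$Sxy <- rowMeans(Xf * Conj(Yf))
  }
  out
}

## Stratified fold assignment: shuffles within class, deals folds round-robin.
stratifiedFolds <- function(labels, k, seed) {
  labels <- as.factor(labels)
  fold <- integer(length(labels))
  set.seed(seed)
  for (cl in levels(labels)) {
    ix <- which(labels == cl)
    ix <- ix[sample.int(length(ix))]
    fold[ix] <- rep_len(seq_len(k), length(ix))
  }
  fold
}

## Centered moving average via cumulative sums; edges use partial windows.
movAvg <- function(x, w) {
  if (w <= 1L) return(x)
  n <- length(x)
  cs <- c(0, cumsum(x))
  h1 <- w %/% 2L
  h2 <- w - h1 - 1L
  lo <- pmax(seq_len(n) - h1, 1L)
  hi <- pmin(seq_len(n) + h2, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

## Low-pass (order-8 Butterworth zero-phase response at 0.4 * new Nyquist)
## and subsample by the integer factor q.
decimateFFT <- function(x, q) {
  if (q <= 1L) return(x)
  fc <- 0.4 / q   # normalized to fs = 1
  y <- .fftApplyMag(x, function(f) 1 / (1 + (f / fc)^16), 1)
  y[seq.int(1L, length(x), by = q)]
}

## First/last index helpers for run detection on a logical vector.
logicalRuns <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}
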
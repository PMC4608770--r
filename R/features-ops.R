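#' Amplitude features of a segment
#'
#' Ten amplitude descriptors: peak (maximum), peak-to-peak, root mean square,
#' mean of local-maximum values, mean of local-minimum values, mean absolute
#' value, and the mean absolute first/second differences of the raw and of the
#' standardized (z-scored) segment. Local extrema are strict sign changes of
#' the first difference; a plateau contributes its first sample.
#'
#' @param x numeric segment.
#' @return named numeric(10): peak, p2p, rms, mlocmaxv, minlocminv, mav,
#'   mavfd, mavfdn, mavsd, mavsdn. Degenerate inputs (length < 3, no extrema,
#'   zero variance for the standardized variants) yield NA for the affected
#'   entries.
#' @examples
#' amplitudeFeatures(c(1, -2, 3))
#' @export
amplitudeFeatures <- function(x) {
  n <- length(x)
  out <- c(peak = NA_real_, p2p = NA_real_, rms = NA_real_,
           mlocmaxv = NA_real_, minlocminv = NA_real_, mav = NA_real_,
           mavfd = NA_real_, mavfdn = NA_real_, mavsd = NA_real_,
           mavsdn = NA_real_)
  if (!n) return(out)
  out["peak"] <- max(x)
  out["p2p"] <- max(x) - min(x)
  out["rms"] <- sqrt(mean(x^2))
  out["mav"] <- mean(abs(x))
  if (n >= 3) {
    ext <- localExtrema(x)
    if (length(ext$max)) out["mlocmaxv"] <- mean(x[ext$max])
    if (length(ext$min)) out["minlocminv"] <- mean(x[ext$min])
    d1 <- diff(x)
    d2 <- diff(d1)
    out["mavfd"] <- mean(abs(d1))
    out["mavsd"] <- mean(abs(d2))
    s <- stats::sd(x)
    if (s > 0) {
      z <- (x - mean(x)) / s
      out["mavfdn"] <- mean(abs(diff(z)))
      out["mavsdn"] <- mean(abs(diff(diff(z))))
    }
  }
  out
}

## Strict local extrema; plateaus contribute their first sample (zero first
## differences are skipped, so the extremum lands right after the last rise
## or fall).
localExtrema <- function(x) {
  s <- sign(diff(x))
  nz <- which(s != 0)
  if (length(nz) < 2L) return(list(max = integer(0), min = integer(0)))
  ss <- s[nz]
  p <- seq_len(length(ss) - 1L)
  list(max = nz[p][ss[p] > 0 & ss[p + 1L] < 0] + 1L,
       min = nz[p][ss[p] < 0 & ss[p + 1L] > 0] + 1L)
}

#' Frequency features of a segment
#'
#' Six spectral descriptors from the one-sided magnitude spectrum of the
#' mean-removed segment: zero crossings, mode frequency (spectral peak), the
#' -3 dB bandwidth (first/last frequencies with magnitude >= 0.707 of the
#' peak), central frequency, amplitude-weighted mean frequency, and the
#' median frequency bisecting the cumulative magnitude.
#'
#' The central frequency is by default the mean of the two band-edge
#' frequencies, (fh + fl) / 2; set \code{cfPrinted = TRUE} for the variant
#' (fh - fl) / 2.
#'
#' @param x numeric segment (length >= 32).
#' @param fs sampling rate in Hz.
#' @param cfPrinted logical, see Details.
#' @return named numeric(6): zc, fmode, bw, cf, fmean, fmed (NA on an all-zero
#'   spectrum).
#' @export
frequencyFeatures <- function(x, fs, cfPrinted = FALSE) {
  out <- c(zc = NA_real_, fmode = NA_real_, bw = NA_real_, cf = NA_real_,
           fmean = NA_real_, fmed = NA_real_)
  n <- length(x)
  if (n < 32) return(out)
  xm <- x - mean(x)
  nzi <- xm[xm != 0]
  out["zc"] <- if (length(nzi) > 1) sum(diff(sign(nzi)) != 0) else 0
  X <- Mod(stats::fft(xm))[seq_len(n %/% 2 + 1L)]
  if (all(X == 0)) return(out)
  f <- (seq_along(X) - 1L) * fs / n
  kmax <- which.max(X)
  out["fmode"] <- f[kmax]
  inBand <- which(X >= 0.707 * X[kmax])
  fl <- f[inBand[1L]]
  fh <- f[inBand[length(inBand)]]
  out["bw"] <- fh - fl
  out["cf"] <- if (cfPrinted) (fh - fl) / 2 else (fh + fl) / 2
  out["fmean"] <- sum(X * f) / sum(X)
  cs <- cumsum(X)
  out["fmed"] <- f[which(cs >= cs[length(cs)] / 2)[1L]]
  out
}

#' Stationarity features of a segment
#'
#' Measures how far the short-time spectrum wanders from the whole-segment
#' spectrum. With spectrogram \eqn{H(\omega, t)} (averaged modified
#' periodogram frames) and full-segment density \eqn{h(\omega)} (the frame
#' mean), the stationarity degree per frequency is
#' \eqn{DS(\omega) = T^{-1} \sum_t (1 - H(\omega, t)/h(\omega))^2}; it is 0
#' for a stationary process. Four aggregates of DS are returned (median,
#' frequency-weighted mean, area, power-weighted area) plus two time-domain
#' descriptors: the standard deviation of per-subsegment means and of
#' per-subsegment standard deviations (subsegments of \code{tiS} seconds).
#'
#' @param x numeric segment.
#' @param fs sampling rate in Hz.
#' @param tiS subsegment length in seconds (default 0.5).
#' @param segLen,overlap spectrogram frame length (samples) and fractional
#'   overlap.
#' @return named numeric(6): median, freqpond, area, area_ponderada, me, sd
#'   (NA when fewer than 4 frames or 2 subsegments are available).
#' @export
stationarityFeatures <- function(x, fs, tiS = 0.5, segLen = 256L,
                                 overlap = 0.5) {
  out <- c(median = NA_real_, freqpond = NA_real_, area = NA_real_,
           area_ponderada = NA_real_, me = NA_real_, sd = NA_real_)
  n <- length(x)
  ## time-domain me / sd
  ni <- as.integer(floor(tiS * fs))
  if (ni >= 2L && n %/% ni >= 2L) {
    k <- n %/% ni
    segs <- matrix(x[seq_len(k * ni)], nrow = ni)
    out["me"] <- stats::sd(colMeans(segs))
    out["sd"] <- stats::sd(apply(segs, 2L, stats::sd))
  }
  if (n < 4L * segLen * (1 - overlap)) return(out)
  xm <- x - mean(x)
  if (all(xm == 0)) {
    out[c("median", "freqpond", "area", "area_ponderada")] <- 0
    return(out)
  }
  ws <- welchSpectra(xm, fs = fs, segLen = segLen, overlap = overlap)
  if (ws$nFrames < 4L) return(out)
  h <- ws$Sxx
  keep <- h > 0
  if (!any(keep)) return(out)
  DS <- rowMeans((1 - ws$frames[keep, , drop = FALSE] / h[keep])^2)
  f <- ws$f[keep]
  dw <- fs / segLen
  out["median"] <- stats::median(DS)
  out["freqpond"] <- sum(f * DS) / sum(f)
  out["area"] <- sum(DS) * dw
  out["area_ponderada"] <- sum(h[keep] * DS) * dw / sum(h[keep])
  out
}

#' Approximate entropy
#'
#' ApEn(m, r) = Phi^m(r) - Phi^(m+1)(r) with Phi^m the mean log fraction of
#' templates within Chebyshev tolerance r, self-matches included (the
#' original convention). Lower values indicate a more regular signal.
#'
#' @param x numeric segment.
#' @param m template length (default 2).
#' @param r tolerance; defaults to \code{rFrac * sd(x)}.
#' @param rFrac tolerance as a fraction of the segment sd (default 0.2).
#' @return numeric(1); 0 for a constant segment; NA when
#'   \code{length(x) <= m + 1}.
#' @export
approximateEntropy <- function(x, m = 2L, r = NULL, rFrac = 0.2) {
  if (is.null(r)) r <- rFrac * stats::sd(x)
  if (length(x) <= m + 1 || is.na(r)) return(.SENTINEL)
  apenC(as.numeric(x), as.integer(m), r)
}

#' Sample entropy
#'
#' SampEn(m, r) = -log(A/B) with B the number of m-length template pairs
#' within Chebyshev tolerance r and A the matching (m+1)-length pairs;
#' self-matches excluded. Shift-invariant.
#'
#' @inheritParams approximateEntropy
#' @return numeric(1); 0 for a constant segment; NA when no template pair
#'   matches or the segment is too short.
#' @export
sampleEntropy <- function(x, m = 2L, r = NULL, rFrac = 0.2) {
  if (is.null(r)) r <- rFrac * stats::sd(x)
  if (length(x) <= m + 1 || is.na(r)) return(.SENTINEL)
  sampenC(as.numeric(x), as.integer(m), r)
}

#' Fuzzy entropy
#'
#' Like sample entropy but templates are baseline-removed (template mean
#' subtracted) and similarity is graded by the fuzzy membership function
#' exp(-(d/r)^n) instead of a hard threshold, making the statistic continuous
#' in the data.
#'
#' @inheritParams approximateEntropy
#' @param n exponent of the fuzzy membership function (default 2).
#' @return numeric(1); 0 for a constant segment.
#' @export
fuzzyEntropy <- function(x, m = 2L, r = NULL, n = 2, rFrac = 0.2) {
  if (is.null(r)) r <- rFrac * stats::sd(x)
  if (length(x) <= m + 1 || is.na(r)) return(.SENTINEL)
  fuzzyenC(as.numeric(x), as.integer(m), r, n)
}

#' Shannon entropy of the amplitude distribution
#'
#' H = -sum(Pk log Pk) over a \code{bins}-bin histogram of the segment values
#' (natural log; empty bins are skipped).
#'
#' @param x numeric segment.
#' @param bins number of histogram bins (default 16).
#' @return numeric(1) in nats; 0 for a constant segment.
#' @export
shannonEntropy <- function(x, bins = 16L) {
  if (!length(x)) return(.SENTINEL)
  rng <- range(x)
  if (rng[1] == rng[2]) return(0)
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  cnt <- tabulate(findInterval(x, edges, rightmost.closed = TRUE,
                               all.inside = TRUE), nbins = bins)
  p <- cnt[cnt > 0] / length(x)
  -sum(p * log(p))
}

#' Normalized spectral entropy
#'
#' Shannon entropy of the normalized one-sided spectral density, divided by
#' log of the number of bins, so the value lies in [0, 1]: near 0 for a pure
#' tone, near 1 for white noise. Invariant to amplitude scaling.
#'
#' @param x numeric segment.
#' @param fs sampling rate in Hz (kept for interface symmetry; the value does
#'   not depend on it).
#' @return numeric(1) in [0, 1]; NA for an all-zero spectrum.
#' @export
spectralEntropy <- function(x, fs) {
  n <- length(x)
  if (n < 8) return(.SENTINEL)
  xm <- x - mean(x)
  P <- Mod(stats::fft(xm))[seq_len(n %/% 2 + 1L)]^2
  tot <- sum(P)
  if (tot == 0) return(.SENTINEL)
  p <- P[P > 0] / tot
  -sum(p * log(p)) / log(length(P))
}

#' Lag-dependence features
#'
#' For each lag k = 1..K the segment is regressed on its k-lagged copy, by a
#' linear fit (ldf) and by a quadratic fit (pldf, the nonlinear variant). With
#' SQT0 the total sum of squares and SQR(k) the residual sum of squares,
#' R0(k) = (SQT0 - SQR(k)) / SQT0, and each feature is the mean over k of
#' sqrt(max(R0(k), 0)). The quadratic nests the linear fit, so pldf >= ldf up
#' to numerical tolerance.
#'
#' @param x numeric segment, length > 10 * K.
#' @param K maximum lag (default 10).
#' @return named numeric(2): ldf, pldf (lags with singular fits are skipped).
#' @export
lagDependenceFeatures <- function(x, K = 10L) {
  n <- length(x)
  if (n <= 10L * K) return(c(ldf = NA_real_, pldf = NA_real_))
  rl <- rq <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    y <- x[(k + 1L):n]
    x0 <- x[seq_len(n - k)]
    yc <- y - mean(y)
    sst <- sum(yc^2)
    xc <- x0 - mean(x0)
    sxx <- sum(xc^2)
    if (sst == 0 || sxx == 0) next
    ## linear and quadratic fits from moments (quadratic nests linear)
    x2 <- xc^2
    x2c <- x2 - mean(x2)
    a11 <- sxx; a12 <- sum(xc * x2c); a22 <- sum(x2c^2)
    b1 <- sum(xc * yc); b2 <- sum(x2c * yc)
    rl[k] <- b1^2 / (sxx * sst)
    det <- a11 * a22 - a12^2
    if (det > 1e-12 * a11 * a22 || (a22 == 0 && a11 > 0)) {
      if (a22 == 0) {
        rq[k] <- rl[k]
      } else {
        c1 <- (a22 * b1 - a12 * b2) / det
        c2 <- (a11 * b2 - a12 * b1) / det
        rq[k] <- (c1 * b1 + c2 * b2) / sst
      }
    }
  }
  c(ldf = mean(sqrt(pmax(rl[!is.na(rl)], 0))),
    pldf = mean(sqrt(pmax(rq[!is.na(rq)], 0))))
}

#' Variability features
#'
#' Unbiased variance (N-1 denominator), standard deviation, range and the
#' semi-interquartile range (Q3 - Q1) / 2.
#'
#' @param x numeric segment (length >= 2).
#' @return named numeric(4): var, std, range, intrange.
#' @export
variabilityFeatures <- function(x) {
  if (length(x) < 2L)
    return(c(var = NA_real_, std = NA_real_, range = NA_real_,
             intrange = NA_real_))
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  v <- stats::var(x)
  c(var = v, std = sqrt(v), range = max(x) - min(x),
    intrange = (q[2] - q[1]) / 2)
}

#' Heart-rate-variability features of a window
#'
#' meanRR (mean interbeat interval), RMSSD (root mean square of successive RR
#' differences, N-1 denominator), and slopeRR (ordinary-least-squares slope of
#' RR against beat index), computed over the RR intervals whose beats fall
#' inside the window.
#'
#' @param rr an \linkS4class{RRSeries}.
#' @param fromS,toS window bounds in seconds; defaults cover the whole series.
#' @return named numeric(3): meanRR, rmssd, slopeRR (ms; NA when fewer than 3
#'   intervals lie in the window).
#' @export
rrFeatures <- function(rr, fromS = -Inf, toS = Inf) {
  out <- c(meanRR = NA_real_, rmssd = NA_real_, slopeRR = NA_real_)
  if (length(rr@beatTimes) < 2L) return(out)
  inWin <- which(rr@beatTimes >= fromS & rr@beatTimes <= toS)
  if (length(inWin) < 2L) return(out)
  v <- rr@rrMs[inWin[-length(inWin)]]
  if (length(v) < 3L) return(out)
  out["meanRR"] <- mean(v)
  out["rmssd"] <- sqrt(sum(diff(v)^2) / (length(v) - 1L))
  ix <- seq_along(v)
  out["slopeRR"] <- sum((ix - mean(ix)) * (v - mean(v))) / sum((ix - mean(ix))^2)
  out
}

#' Magnitude-squared-coherence similarity features
#'
#' Coherence between a window segment and the subject's mean baseline
#' segment, C(f) = |Sxy|^2 / (Sxx Syy), estimated with averaged overlapping
#' modified periodograms. Four aggregates in [0, 1] are returned: C at the
#' median frequency of the segment's spectrum, the plain mean of C, the
#' power-weighted mean, and the power-weighted (trapezoidal) area.
#'
#' @param x window segment.
#' @param y baseline reference segment (equal length).
#' @param fs sampling rate in Hz.
#' @param segLen,overlap Welch segment length (samples) and fractional
#'   overlap.
#' @return named numeric(4): cohe_f_median, cohe_mean, cohe_pond_mean,
#'   cohe_area_pond (NA when fewer than 4 averaging frames are available -
#'   the coherence of a single frame is identically 1).
#' @export
coherenceFeatures <- function(x, y, fs, segLen = 256L, overlap = 0.5) {
  out <- c(cohe_f_median = NA_real_, cohe_mean = NA_real_,
           cohe_pond_mean = NA_real_, cohe_area_pond = NA_real_)
  stopifnot(length(x) == length(y))
  ws <- welchSpectra(x - mean(x), y - mean(y), fs = fs, segLen = segLen,
                     overlap = overlap)
  if (ws$nFrames < 4L) return(out)
  den <- ws$Sxx * ws$Syy
  keep <- den > 0
  if (!any(keep)) return(out)
  C <- Mod(ws$Sxy[keep])^2 / den[keep]
  Sxx <- ws$Sxx[keep]
  f <- ws$f[keep]
  cs <- cumsum(Sxx)
  med <- which(cs >= cs[length(cs)] / 2)[1L]
  out["cohe_f_median"] <- C[med]
  out["cohe_mean"] <- mean(C)
  out["cohe_pond_mean"] <- sum(Sxx * C) / sum(Sxx)
  trapz <- function(fx, gy) sum(diff(fx) * (utils::head(gy, -1) + utils::tail(gy, -1)) / 2)
  out["cohe_area_pond"] <- trapz(f, Sxx * C) / trapz(f, Sxx)
  out
}

#' Pearson similarity to the mean baseline signal
#'
#' @param x window segment.
#' @param y baseline reference segment (equal length).
#' @return numeric(1) in [-1, 1]; NA when either side has zero variance.
#' @export
similarityCorrelation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(.SENTINEL)
  stats::cor(x, y)
}

#' Histogram mutual information
#'
#' I(A, B) = H(A) + H(B) - H(A, B) from a bins x bins joint histogram (each
#' margin binned over its own range), in nats. Symmetric and non-negative up
#' to estimator noise.
#'
#' @param x,y equal-length numeric segments.
#' @param bins histogram bins per margin (default 16).
#' @return numeric(1) in nats.
#' @export
mutualInformation <- function(x, y, bins = 16L) {
  stopifnot(length(x) == length(y))
  bx <- .binIndex(x, bins)
  by <- .binIndex(y, bins)
  joint <- tabulate((bx - 1L) * bins + by, nbins = bins * bins) / length(x)
  px <- tabulate(bx, nbins = bins) / length(x)
  py <- tabulate(by, nbins = bins) / length(y)
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  H(px) + H(py) - H(joint)
}

.binIndex <- function(x, bins) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(1L, length(x)))
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
}
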
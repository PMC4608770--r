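test_that("band-pass filter matches the Butterworth magnitude oracle", {
  fs <- 512
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  ## forward-backward amplitude response of the HP(20) + LP(250) cascade
  mag <- function(f, lo = 20, hi = 250, o = 4)
    (1 / (1 + (lo / f)^(2 * o))) * (1 / (1 + (f / hi)^(2 * o)))
  x100 <- sin(2 * pi * 100 * t)
  r100 <- sqrt(mean(butterworthBandpass(x100, fs, 20, 250)^2)) /
    sqrt(mean(x100^2))
  expect_equal(r100, mag(100), tolerance = 0.02)
  expect_gt(r100, 0.95)   # pass band within 5% of unity
  x5 <- sin(2 * pi * 5 * t)
  expect_lt(sqrt(mean(butterworthBandpass(x5, fs, 20, 250)^2)) /
              sqrt(mean(x5^2)), 0.05)
  expect_identical(butterworthBandpass(numeric(100), fs, 20, 250),
                   numeric(100))
  expect_error(butterworthBandpass(rnorm(10), fs, 250, 20), "lo < hi")
  expect_warning(butterworthBandpass(rnorm(512), 400, 0.1, 250), "Nyquist")
})

test_that("EMD denoising improves a noisy tone and passes clean input", {
  fs <- 512
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  target <- sin(2 * pi * 50 * t)
  set.seed(11)
  improved <- vapply(1:10, function(i) {
    noisy <- target + rnorm(length(t), 0, sd(target))   # SNR 0 dB
    cor(emdDenoise(noisy, fs), target) > cor(noisy, target)
  }, logical(1))
  expect_gte(mean(improved), 0.8)

  clean <- sin(2 * pi * 50 * t)
  expect_gt(cor(emdDenoise(clean, fs), clean), 0.99)
  expect_identical(emdDenoise(rep(3, 512), fs), rep(3, 512))
  expect_error(emdDenoise(rnorm(32), fs), "64")
})

test_that("Hilbert burst detector locates bursts and controls false alarms", {
  fs <- 512
  cfg <- simConfig(trialSdLog = 0, emgToneSdLog = 0, emgSpontRate = 0,
                   emgBurstGain = c(4, 4, 4, 4))
  sched <- stimulusSchedule(data.frame(level = "T4", onset_s = 10,
                                       plateau_s = 2))
  set.seed(12)
  x <- synthEMG(sched, "emg_zyg", cfg, nSamples = as.integer(20 * fs))
  bursts <- detectBurstsHilbert(x, fs)
  expect_equal(nrow(bursts), 1L)
  expect_lt(abs(bursts$onset_s[1] - 10), 0.25)

  set.seed(13)
  fp <- vapply(1:100, function(i) {
    noise <- synthEMG(stimulusSchedule(data.frame(level = character(0),
                                                  onset_s = numeric(0),
                                                  plateau_s = numeric(0))),
                      "emg_zyg", cfg, nSamples = as.integer(8 * fs))
    nrow(detectBurstsHilbert(noise, fs, k = 3.5))
  }, numeric(1))
  expect_gte(mean(fp == 0), 0.95)
  expect_equal(nrow(detectBurstsHilbert(numeric(512), fs)), 0L)
})

test_that("window cutting yields the protocol's labelled class counts", {
  cfg <- simConfig()
  sched <- generateSchedule(cfg, seed = 20)
  n <- as.integer(painsig:::recordingDuration(sched, cfg@windowS) * cfg@fs)
  zeros <- lapply(1:5, function(i) numeric(n))
  names(zeros) <- c("emg_zyg", "emg_cor", "emg_tra", "scl", "ecg")
  rec <- bioRecording("s", cfg@fs, zeros)
  ws <- cutWindows(rec, sched, 5.5)
  expect_length(classLabels(ws), 100L)
  expect_equal(as.integer(table(classLabels(ws))), rep(20L, 5))
  expect_equal(nrow(ws@channels$emg_zyg), 2816L)   # 5.5 s x 512 Hz

  ## an event too close to the recording end is dropped with a warning
  shortRec <- bioRecording("s", cfg@fs, lapply(zeros, function(z)
    z[seq_len(as.integer((max(stimulusEvents(sched)$onset_s) + 1) * cfg@fs))]))
  expect_warning(ws2 <- cutWindows(shortRec, sched, 5.5), "dropped")
  expect_lt(length(classLabels(ws2)), 100L)
})

test_that("QRS detection recovers clean, gappy and degenerate trains", {
  fs <- 512
  tpl <- function(n, beats) {
    x <- numeric(n)
    tt <- seq(-0.04, 0.04, by = 1 / fs)
    q <- (1 - (tt / 0.01)^2) * exp(-tt^2 / (2 * 0.01^2))
    for (b in beats) {
      i <- round(b * fs) + seq_along(q) - (length(q) %/% 2)
      ok <- i >= 1 & i <= n
      x[i[ok]] <- x[i[ok]] + q[ok]
    }
    x
  }
  beats <- seq(0.5, 19.5, by = 0.8)
  rr <- detectRR(tpl(20 * fs, beats), fs)
  expect_equal(length(rr@beatTimes), length(beats))
  expect_true(all(abs(rr@rrMs - 800) <= 1000 / fs))

  gappy <- beats[-10]   # one missing beat
  rrg <- detectRR(tpl(20 * fs, gappy), fs)
  expect_equal(sum(abs(rrg@rrMs - 1600) < 3), 1L)
  expect_equal(sum(abs(rrg@rrMs - 800) < 3), length(gappy) - 2L)

  expect_length(detectRR(numeric(5120), fs)@rrMs, 0L)
})

test_that("preprocessing assembles denoised windows with beat times", {
  cfg <- tinySimConfig()
  sub <- simulateSubject(cfg, 1L)
  ws <- preprocessRecording(sub$recording, sub$schedule,
                            windowS = cfg@windowS)
  expect_s4_class(ws, "LabeledWindowSet")
  expect_equal(length(classLabels(ws)),
               nrow(stimulusEvents(sub$schedule)) +
                 length(baselineOnsets(sub$schedule)))
  expect_gt(length(ws@beatTimes), 10)
  ## without EMD the EMG segments keep only the 20-250 Hz band
  wsF <- preprocessRecording(sub$recording, sub$schedule,
                             windowS = cfg@windowS, emd = FALSE)
  seg <- wsF@channels$emg_zyg[, 1]
  P <- Mod(fft(seg - mean(seg)))^2
  f <- (seq_along(P) - 1) * cfg@fs / length(P)
  low <- sum(P[f > 0.5 & f < 10]) / sum(P[f > 0.5 & f < cfg@fs / 2])
  expect_lt(low, 0.01)
  ## EMD denoising preserves the amplitude ordering that carries the class
  ## signal even on noise-like EMG (the broadband IMFs are noise-consistent)
  rmsD <- apply(ws@channels$emg_zyg, 2, sd)
  rmsF <- apply(wsF@channels$emg_zyg, 2, sd)
  expect_gt(cor(rmsD, rmsF, method = "spearman"), 0.7)
})
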
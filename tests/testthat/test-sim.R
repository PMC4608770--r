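test_that("generated schedules follow the randomized phasic heat protocol", {
  sched <- generateSchedule(simConfig(), seed = 1)
  ev <- stimulusEvents(sched)
  expect_equal(nrow(ev), 80L)
  expect_equal(as.integer(table(ev$level)), rep(20L, 4))
  expect_length(baselineOnsets(sched), 20L)
  expect_true(all(ev$plateau_s == 4))

  small <- generateSchedule(simConfig(repsPerLevel = 1, nBaseline = 1),
                            seed = 1)
  expect_equal(nrow(stimulusEvents(small)), 4L)
})

test_that("inter-stimulus pauses are uniform within the configured bounds", {
  pauses <- unlist(lapply(1:13, function(s) {
    ev <- stimulusEvents(generateSchedule(simConfig(), seed = s))
    ev$onset_s[-1] - (ev$onset_s[-nrow(ev)] + ev$plateau_s[-nrow(ev)])
  }))
  expect_gte(length(pauses), 1000L)
  expect_true(all(pauses >= 8 & pauses <= 12))
  ## baseline windows sit inside pauses, clear of the stimuli
  sched <- generateSchedule(simConfig(), seed = 2)
  ev <- stimulusEvents(sched)
  for (b in baselineOnsets(sched)) {
    prev <- max(ev$onset_s[ev$onset_s < b])
    expect_gte(b, prev + 4 + 1.5)
  }
})

test_that("EMG synthesis scales noise by class-dependent burst gains", {
  cfg <- simConfig(repsPerLevel = 5, nBaseline = 5, trialSdLog = 0,
                   emgToneSdLog = 0, emgSpontRate = 0,
                   emgBurstGain = c(3, 3, 3, 3))
  sched <- generateSchedule(cfg, seed = 8)
  x <- synthEMG(sched, "emg_zyg", cfg, seed = 8)
  rec <- bioRecording("s", cfg@fs, list(emg_zyg = x, emg_cor = x,
                                        emg_tra = x, scl = x, ecg = x))
  ws <- cutWindows(rec, sched, cfg@windowS)
  rms <- apply(ws@channels$emg_zyg, 2, function(v) sqrt(mean(v^2)))
  lab <- as.character(classLabels(ws))
  expect_gt(mean(outer(rms[lab == "T4"], rms[lab == "B"], ">")), 0.95)
})

test_that("unit-gain EMG is stationary noise with no bursts and zero mean", {
  cfg <- simConfig(repsPerLevel = 5, nBaseline = 5, trialSdLog = 0,
                   emgToneSdLog = 0, emgSpontRate = 0,
                   emgBurstGain = c(1, 1, 1, 1))
  sched <- generateSchedule(cfg, seed = 9)
  x <- synthEMG(sched, "emg_zyg", cfg, seed = 9)
  rec <- bioRecording("s", cfg@fs, list(emg_zyg = x, emg_cor = x,
                                        emg_tra = x, scl = x, ecg = x))
  ws <- cutWindows(rec, sched, cfg@windowS)
  nBursty <- sum(apply(ws@channels$emg_zyg, 2, function(v)
    nrow(detectBurstsHilbert(v, cfg@fs)) > 0))
  expect_lte(nBursty / ncol(ws@channels$emg_zyg), 0.05)

  empty <- stimulusSchedule(data.frame(level = character(0),
                                       onset_s = numeric(0),
                                       plateau_s = numeric(0)))
  y <- synthEMG(empty, "emg_zyg", cfg, seed = 10, nSamples = 2^15)
  expect_lt(abs(mean(y)), 4 * cfg@emgSigma / sqrt(length(y)))
})

test_that("SCL synthesis produces latency-bound phasic responses", {
  cfg <- simConfig(sclSpontRate = 0, sclDriftSd = 0, sclNoise = 0,
                   trialSdLog = 0, sclPhasicAmp = c(1, 1, 1, 1))
  one <- stimulusSchedule(data.frame(level = "T4", onset_s = 10,
                                     plateau_s = 4))
  x <- synthSCL(one, cfg, seed = 4, nSamples = as.integer(40 * cfg@fs))
  tmax <- (which.max(x) - 1) / cfg@fs
  expect_gte(tmax - 10, 1.8)   # latency >= 1 s plus kernel rise time
  expect_lte(tmax - 10, 4.7)   # latency <= 3 s plus slowest rise

  flat <- synthSCL(one, simConfig(sclSpontRate = 0, sclDriftSd = 0,
                                  sclNoise = 0.02,
                                  sclPhasicAmp = c(0, 0, 0, 0)),
                   seed = 4, nSamples = as.integer(40 * cfg@fs))
  expect_lt(diff(range(flat)), 0.25)   # tonic-only trace
})

test_that("mean SCL peak-to-peak grows monotonically with stimulus level", {
  cfg <- simConfig(repsPerLevel = 20, nBaseline = 5, sclSpontRate = 0,
                   sclDriftSd = 0, trialSdLog = 0.2)
  sched <- generateSchedule(cfg, seed = 5)
  x <- synthSCL(sched, cfg, seed = 5)
  rec <- bioRecording("s", cfg@fs, list(emg_zyg = x, emg_cor = x,
                                        emg_tra = x, scl = x, ecg = x))
  ws <- cutWindows(rec, sched, cfg@windowS)
  lab <- as.character(classLabels(ws))
  p2p <- apply(ws@channels$scl, 2, function(v) max(v) - min(v))
  means <- tapply(p2p, lab, mean)[c("T1", "T2", "T3", "T4")]
  expect_true(all(diff(means) > 0))
})

test_that("ECG synthesis controls the recovered RR structure", {
  cfg <- simConfig(sdnn = 0, rrShortening = c(0, 0, 0, 0), rrTrialSd = 0,
                   ecgNoise = 0, meanRR = 800)
  empty <- stimulusSchedule(data.frame(level = character(0),
                                       onset_s = numeric(0),
                                       plateau_s = numeric(0)))
  x <- synthECG(empty, cfg, seed = 6, nSamples = as.integer(30 * cfg@fs))
  rr <- detectRR(x, cfg@fs)
  expect_gt(length(rr@rrMs), 20)
  expect_true(all(abs(rr@rrMs - 800) <= 1000 / cfg@fs))
  feats <- rrFeatures(rr)
  ## detection quantizes beats to the sample grid, so the recovered RMSSD is
  ## bounded by the sampling period rather than exactly zero
  expect_lt(unname(feats["rmssd"]), 2 * 1000 / cfg@fs)

  ## stimulus windows shorten the mean RR
  cfgS <- simConfig(repsPerLevel = 10, nBaseline = 10, rrTrialSd = 0,
                    rrShortening = c(60, 60, 60, 60), sdnn = 10,
                    ecgNoise = 0)
  hits <- vapply(1:5, function(s) {
    sched <- generateSchedule(cfgS, seed = 100 + s)
    x <- synthECG(sched, cfgS, seed = 100 + s)
    rr <- detectRR(x, cfgS@fs)
    ev <- stimulusEvents(sched)
    inWin <- function(on) {
      i <- rr@beatTimes[-length(rr@beatTimes)]
      rr@rrMs[i >= on & i <= on + cfgS@windowS]
    }
    stim <- unlist(lapply(ev$onset_s[ev$level == "T4"], inWin))
    base <- unlist(lapply(baselineOnsets(sched), inWin))
    mean(stim) < mean(base)
  }, logical(1))
  expect_gte(sum(hits), 5 * 0.95)
})

test_that("dataset generation is deterministic and subject-reproducible", {
  cfg <- simConfig(nSubjects = 2, repsPerLevel = 1, nBaseline = 1, seed = 77)
  d1 <- generateDataset(cfg)
  d2 <- generateDataset(cfg)
  expect_identical(d1, d2)
  expect_length(d1, 2L)
  ## any single subject regenerates in isolation
  s2 <- simulateSubject(cfg, 2L)
  expect_identical(s2$recording, d1[[2]]$recording)
  expect_false(identical(d1[[1]]$recording@channels$ecg,
                         d1[[2]]$recording@channels$ecg))
})
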
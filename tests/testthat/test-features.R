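test_that("amplitude features match hand arithmetic and a brute-force oracle", {
  cst <- amplitudeFeatures(rep(2.5, 20))
  expect_equal(unname(cst[c("peak", "p2p", "rms", "mavfd", "mavsd")]),
               c(2.5, 0, 2.5, 0, 0))
  v <- amplitudeFeatures(c(1, -2, 3))
  expect_equal(unname(v["p2p"]), 5)
  expect_equal(unname(v["mav"]), 2)
  expect_equal(unname(v["mavfd"]), 4)   # (|-3| + |5|) / 2
  set.seed(21)
  for (i in 1:100) {
    x <- rnorm(30 + i %% 20)
    expect_equal(amplitudeFeatures(x), amplitudeOracle(x), tolerance = 1e-12)
    expect_equal(amplitudeFeatures(2 * x)[c("peak", "rms", "mav")],
                 2 * amplitudeOracle(x)[c("peak", "rms", "mav")],
                 tolerance = 1e-12)
  }
})

test_that("amplitude and variability features are time-reversal invariant", {
  set.seed(22)
  for (i in 1:20) {
    x <- rnorm(200)
    expect_equal(amplitudeFeatures(x)[c("peak", "p2p", "rms", "mav",
                                        "mavfd", "mavsd")],
                 amplitudeFeatures(rev(x))[c("peak", "p2p", "rms", "mav",
                                             "mavfd", "mavsd")],
                 tolerance = 1e-12)
    expect_equal(variabilityFeatures(x), variabilityFeatures(rev(x)),
                 tolerance = 1e-12)
  }
})

test_that("frequency features recover the spectral content of known tones", {
  fs <- 512
  t <- seq(0, 5.5 - 1 / fs, by = 1 / fs)
  df <- 1 / 5.5
  v <- frequencyFeatures(sin(2 * pi * 50 * t), fs)
  expect_lt(abs(v["fmode"] - 50), df + 1e-9)
  expect_lt(abs(v["fmean"] - 50), 2 * df)
  expect_lt(abs(v["fmed"] - 50), df + 1e-9)
  expect_lte(abs(v["zc"] - 2 * 50 * 5.5), 1)
  ## equal-power tones at 40 and 60 Hz: symmetric mean frequency
  v2 <- frequencyFeatures(sin(2 * pi * 40 * t) + sin(2 * pi * 60 * t), fs)
  expect_lt(abs(v2["fmean"] - 50), 2 * df)
  ## white noise: median frequency near fs / 4
  set.seed(23)
  meds <- vapply(1:10, function(i)
    frequencyFeatures(rnorm(2816), fs)["fmed"], numeric(1))
  expect_lt(abs(mean(meds) - fs / 4), 0.1 * fs / 4)
})

test_that("central frequency follows the textual and printed variants", {
  fs <- 512
  t <- seq(0, 5.5 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 40 * t) + sin(2 * pi * 60 * t)
  vt <- frequencyFeatures(x, fs, cfPrinted = FALSE)
  vp <- frequencyFeatures(x, fs, cfPrinted = TRUE)
  ## the band edges are the two tones, so the variants differ by fl
  expect_equal(unname(vt["cf"]), 50, tolerance = 0.05)
  expect_equal(unname(vp["cf"]), unname(vp["bw"]) / 2, tolerance = 1e-9)
})

test_that("stationarity features separate stationary from modulated noise", {
  fs <- 512
  set.seed(24)
  areas <- t(vapply(1:20, function(i) {
    stat <- rnorm(2816)
    mod <- c(rnorm(1408), 2 * rnorm(1408))   # variance step mid-segment
    c(stationarityFeatures(stat, fs)["area"],
      stationarityFeatures(mod, fs)["area"])
  }, numeric(2)))
  expect_true(all(areas[, 2] > areas[, 1]))
  cst <- stationarityFeatures(rep(1, 2816), fs)
  expect_equal(unname(cst["me"]), 0)
  expect_equal(unname(cst["sd"]), 0)
  ## white noise: me and sd shrink as subsegments lengthen
  x <- rnorm(2816)
  expect_lt(stationarityFeatures(x, fs, tiS = 2.5)["me"],
            stationarityFeatures(x, fs, tiS = 0.1)["me"] + 0.05)
})

test_that("template entropies equal their brute-force oracles", {
  x <- rep(c(85, 80, 89), 17)
  r <- 0.2 * sd(x)
  expect_lt(abs(approximateEntropy(x, 2, r) - apenOracle(x, 2, r)), 1e-10)
  expect_lt(abs(sampleEntropy(x, 2, r) - sampenOracle(x, 2, r)), 1e-10)
  expect_lt(abs(fuzzyEntropy(x, 2, r, 2) - fuzzyenOracle(x, 2, r, 2)), 1e-10)
  set.seed(25)
  for (i in 1:5) {
    y <- rnorm(50)
    r <- 0.5 * sd(y)   # wide tolerance so template matches exist at n = 50
    expect_lt(abs(approximateEntropy(y, 2, r) - apenOracle(y, 2, r)), 1e-10)
    expect_lt(abs(sampleEntropy(y, 2, r) - sampenOracle(y, 2, r)), 1e-10)
    expect_lt(abs(fuzzyEntropy(y, 2, r, 2) - fuzzyenOracle(y, 2, r, 2)),
              1e-10)
  }
})

test_that("entropies are zero on constant input and order noise above tones", {
  cst <- rep(4.2, 60)
  expect_equal(approximateEntropy(cst), 0)
  expect_equal(sampleEntropy(cst), 0)
  expect_equal(fuzzyEntropy(cst), 0)
  expect_equal(shannonEntropy(cst), 0)
  set.seed(26)
  t <- seq(0, 2, length.out = 300)
  wins <- vapply(1:20, function(i) {
    noise <- rnorm(300)
    tone <- sqrt(2) * sin(2 * pi * 7 * t + runif(1, 0, 2 * pi))
    approximateEntropy(noise) > approximateEntropy(tone)
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("sample entropy is shift-invariant, fuzzy entropy is continuous", {
  set.seed(27)
  for (i in 1:20) {
    x <- rnorm(80)
    r <- 0.2 * sd(x)
    expect_equal(sampleEntropy(x, 2, r), sampleEntropy(x + 100, 2, r),
                 tolerance = 1e-12)
  }
  x <- rnorm(120)
  r <- 0.2 * sd(x)
  f0 <- fuzzyEntropy(x, 2, r, 2)
  xp <- x
  xp[60] <- xp[60] + 0.01 * sd(x)
  expect_lt(abs(fuzzyEntropy(xp, 2, r, 2) - f0) / abs(f0), 0.1)
})

test_that("histogram and spectral entropies match their closed forms", {
  two <- c(rep(0, 40), rep(1, 40))
  expect_equal(shannonEntropy(two, bins = 2), log(2), tolerance = 1e-12)
  set.seed(28)
  u <- runif(20000)
  B <- 16
  edges <- seq(min(u), max(u), length.out = B + 1)
  cnt <- tabulate(findInterval(u, edges, rightmost.closed = TRUE,
                               all.inside = TRUE), B)
  p <- cnt / length(u)
  expect_equal(shannonEntropy(u, B), -sum(p * log(p)), tolerance = 1e-12)
  expect_lt(abs(shannonEntropy(u, B) - log(B)), 0.01)

  fs <- 512
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  expect_lt(spectralEntropy(sin(2 * pi * 64 * t), fs), 0.2)
  set.seed(29)
  expect_gt(spectralEntropy(rnorm(2816), fs), 0.85)
  x <- rnorm(500)
  expect_equal(spectralEntropy(x, fs), spectralEntropy(7 * x, fs),
               tolerance = 1e-12)
})

test_that("lag-dependence features detect autocorrelation structure", {
  set.seed(30)
  ar <- as.numeric(arima.sim(list(ar = 0.9), 2000))
  v <- lagDependenceFeatures(ar, 10)
  expect_gt(v["ldf"], 0.5)
  wn <- lagDependenceFeatures(rnorm(2000), 10)
  expect_lt(wn["ldf"], 0.1)
  for (i in 1:20) {
    x <- rnorm(300)
    lv <- lagDependenceFeatures(x, 5)
    expect_gte(lv["pldf"], lv["ldf"] - 1e-8)   # quadratic nests linear
  }
})

test_that("variability features match hand arithmetic and quantile theory", {
  v <- variabilityFeatures(1:5)
  expect_equal(unname(v["var"]), 2.5)
  expect_equal(unname(v["std"]), sqrt(2.5))
  expect_equal(unname(v["range"]), 4)
  expect_equal(unname(variabilityFeatures(rep(3, 10))), rep(0, 4))
  set.seed(31)
  z <- rnorm(1e5)
  expect_equal(unname(variabilityFeatures(z)["intrange"]), 0.6745,
               tolerance = 0.03)
})

test_that("RR features match hand arithmetic", {
  rr3 <- new("RRSeries", beatTimes = c(1, 1.8, 2.6, 3.4),
             rrMs = c(800, 800, 800))
  f <- rrFeatures(rr3)
  expect_equal(unname(f), c(800, 0, 0))
  rr4 <- new("RRSeries", beatTimes = c(1, 1.8, 2.61, 3.4),
             rrMs = c(800, 810, 790))
  expect_equal(unname(rrFeatures(rr4)["rmssd"]), sqrt(250),
               tolerance = 1e-9)
  rr5 <- new("RRSeries", beatTimes = cumsum(c(1, 0.7, 0.71, 0.72, 0.73)),
             rrMs = c(700, 710, 720, 730))
  expect_equal(unname(rrFeatures(rr5)["slopeRR"]), 10, tolerance = 1e-9)
  expect_true(all(is.na(rrFeatures(new("RRSeries", beatTimes = numeric(0),
                                       rrMs = numeric(0))))))
})

test_that("coherence aggregates behave for identical, independent and delayed signals", {
  fs <- 512
  set.seed(32)
  x <- rnorm(2816)
  same <- coherenceFeatures(x, x, fs)
  expect_equal(unname(same), rep(1, 4), tolerance = 1e-10)
  ind <- replicate(10, mean(coherenceFeatures(rnorm(2816), rnorm(2816),
                                              fs)["cohe_mean"]))
  expect_lt(mean(ind), 0.3)
  y <- c(rep(0, 10), x[1:(2816 - 10)])   # pure delay
  del <- coherenceFeatures(x, y, fs)
  expect_gt(min(del), 0.9)
  ## a single averaging frame would be identically 1: sentinel instead
  expect_true(all(is.na(coherenceFeatures(rnorm(300), rnorm(300), fs,
                                          segLen = 256))))
})

test_that("similarity correlation and mutual information follow theory", {
  set.seed(33)
  x <- rnorm(2816)
  expect_equal(similarityCorrelation(x, x), 1)
  expect_equal(similarityCorrelation(x, -x), -1)
  expect_true(is.na(similarityCorrelation(x, rep(1, 2816))))
  nullr <- vapply(1:50, function(i)
    abs(similarityCorrelation(rnorm(2816), rnorm(2816))), numeric(1))
  expect_gte(mean(nullr < 0.06), 0.95)

  expect_equal(mutualInformation(x, x, 16), shannonEntropy(x, 16),
               tolerance = 1e-12)
  mis <- vapply(1:20, function(i)
    mutualInformation(rnorm(2816), rnorm(2816), 16), numeric(1))
  expect_lt(mean(mis), 0.05)
  expect_gte(min(mis), -1e-12)
  for (i in 1:20) {
    a <- rnorm(500); b <- rnorm(500)
    expect_equal(mutualInformation(a, b), mutualInformation(b, a),
                 tolerance = 1e-12)
  }
})

test_that("the extracted vector has the canonical 159-name structure", {
  ws <- makeWindowSet(nWindows = 10)
  fm <- extractFeatures(ws)
  expect_equal(nrow(fm), 159L)
  grp <- table(painsig:::featureGroupOf(rownames(fm)))
  expect_equal(as.integer(grp[c("Amplitude", "Frequency", "Stationarity",
                            "Entropy", "Linearity", "Variability",
                            "Similarity")]),
               c(40L, 24L, 24L, 20L, 8L, 19L, 24L))
  expect_true(all(c("Zygomaticus_Similarity_Correlation",
                    "Corrugator_Amplitude_Peak") %in% rownames(fm)))
  ## four waveform channels only: 4 x 39 = 156 features
  ws4 <- makeWindowSet(nWindows = 10, roles = c("emg_zyg", "emg_cor",
                                                "emg_tra", "scl"))
  expect_equal(nrow(extractFeatures(ws4)), 156L)
})

test_that("per-person z-normalization standardizes within subject", {
  fmA <- extractFeatures(makeWindowSet(nWindows = 8, seed = 1))
  fmB <- extractFeatures(makeWindowSet(nWindows = 8, seed = 2))
  SummarizedExperiment::colData(fmB)$subject_id <- "SYN2"
  colnames(fmB) <- paste0("b", seq_len(ncol(fmB)))
  fm <- combineFeatureMatrices(fmA, fmB)
  fz <- znormPerPerson(fm)
  v <- SummarizedExperiment::assay(fz, "features")
  subj <- SummarizedExperiment::colData(fz)$subject_id
  for (s in unique(subj)) {
    m <- v[, subj == s]
    mu <- rowMeans(m, na.rm = TRUE)
    sg <- apply(m, 1, sd, na.rm = TRUE)
    ok <- !is.na(sg) & sg > 0
    expect_lt(max(abs(mu[ok])), 1e-10)
    expect_lt(max(abs(sg[ok] - 1)), 1e-10)
  }
  ## single subject: equals global z-scoring
  fzA <- znormPerPerson(fmA)
  vA <- SummarizedExperiment::assay(fmA, "features")
  manual <- t(scale(t(vA)))
  got <- SummarizedExperiment::assay(fzA, "features")
  ## exclude rows that are (numerically) constant within the subject
  ok <- apply(vA, 1, sd) > pmax(abs(rowMeans(vA)), 1) * 1e-10
  expect_equal(got[ok, ], manual[ok, ], tolerance = 1e-10,
               ignore_attr = TRUE)
})
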
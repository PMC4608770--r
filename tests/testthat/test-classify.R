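test_that("stratified splitting reproduces the protocol arithmetic", {
  fm <- makeRandomFeatureMatrix(nFeat = 5, nSubjects = 85, perClass = 20)
  expect_equal(ncol(fm), 8500L)
  parts <- splitData(fm, splitSpec(seed = 1))
  expect_equal(ncol(parts$train), 6375L)
  expect_equal(ncol(parts$test), 2125L)
  expect_equal(as.integer(table(classLabels(parts$train))), rep(1275L, 5))
  ## same seed, identical split
  parts2 <- splitData(fm, splitSpec(seed = 1))
  expect_identical(parts$trainIdx, parts2$trainIdx)

  small <- makeRandomFeatureMatrix(nFeat = 3, nSubjects = 1, perClass = 1)
  expect_error(splitData(small[, classLabels(small) %in% c("B", "T1")]),
               "at least 4")
  ## n = 8, two balanced classes: 6 train / 2 test, both classes present
  m8 <- painFeatureMatrix(matrix(rnorm(16), 2,
                                 dimnames = list(c("a", "b"), NULL)),
                          rep("s", 8), rep(c("B", "T4"), 4))
  p8 <- splitData(m8, splitSpec(seed = 2))
  expect_equal(ncol(p8$train), 6L)
  expect_setequal(as.character(unique(classLabels(p8$test))), c("B", "T4"))
})

test_that("grouped splitting keeps whole subjects together", {
  fm <- makeRandomFeatureMatrix(nFeat = 4, nSubjects = 8, perClass = 5)
  parts <- splitData(fm, splitSpec(seed = 3, groupBySubject = TRUE))
  trS <- unique(SummarizedExperiment::colData(parts$train)$subject_id)
  teS <- unique(SummarizedExperiment::colData(parts$test)$subject_id)
  expect_length(intersect(trS, teS), 0L)
  expect_equal(length(trS), 6L)
})

test_that("grid search attains the Bayes-like rate on a separable fixture", {
  set.seed(51)
  n <- 200
  y <- rep(c("B", "T4"), each = n / 2)
  x <- matrix(rnorm(n * 4), n, 4)
  x[y == "T4", ] <- x[y == "T4", ] + 2.5
  gs <- gridSearchTrain(x, y, svmConfig(), seed = 1)
  expect_gte(gs$cvAccuracy, 0.95)
  expect_true(gs$C %in% svmConfig()@cGrid)
  expect_true(gs$gamma %in% svmConfig()@gammaGrid)
  ## permuted labels: chance-level cross-validated accuracy
  yp <- sample(y)
  gsp <- gridSearchTrain(x, yp, svmConfig(cGrid = 2^c(-3, 1, 5),
                                          gammaGrid = 2^c(-9, -5, -1)),
                         seed = 1)
  expect_lt(abs(gsp$cvAccuracy - 0.5), 0.12)
})

test_that("evaluation reproduces the printed-style confusion arithmetic", {
  ## confusion [[TP=45, FN=5], [FP=10, TN=40]]
  truth <- c(rep("pos", 50), rep("neg", 50))
  pred <- c(rep("pos", 45), rep("neg", 5), rep("pos", 10), rep("neg", 40))
  ev <- evaluateModel(pred, truth)
  expect_equal(accuracy(ev), 0.85)
  expect_equal(unname(sensitivity(ev)["pos"]), 0.90)
  expect_equal(unname(specificity(ev)["pos"]), 0.80)

  perf <- evaluateModel(truth, truth)
  expect_equal(accuracy(perf), 1)
  expect_equal(unname(sensitivity(perf)), c(1, 1))
  expect_equal(perf@cramersV, 1)

  const <- evaluateModel(rep("B", 40), rep(c("B", "T4"), 20))
  expect_equal(accuracy(const), 0.5)
  expect_equal(unname(sensitivity(const)["B"]), 1)
  expect_equal(unname(sensitivity(const)["T4"]), 0)
})

test_that("Cramer's V matches hand-computed chi-squared values and bands", {
  expect_equal(cramersV(diag(c(30, 30))), 1)
  expect_identical(cramersVBand(1), "very strong")
  v <- cramersV(matrix(c(40, 20, 10, 30), 2))
  expect_equal(v, sqrt(100 * (40 * 30 - 10 * 20)^2 /
                         (50 * 50 * 60 * 40) / 100), tolerance = 1e-12)
  expect_equal(v, 0.40824829, tolerance = 1e-6)
  expect_identical(cramersVBand(v), "relatively strong")
  ## independent margins: V = 0
  ind <- outer(c(10, 20), c(6, 4))
  expect_equal(cramersV(ind), 0, tolerance = 1e-12)
  expect_true(is.na(cramersV(matrix(c(5, 3, 0, 0), 2))))
  expect_identical(cramersVBand(0.05), "negligible")
  expect_identical(cramersVBand(0.25), "moderate")
})

test_that("accuracy decomposes over per-class sensitivities", {
  set.seed(52)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    n <- 200
    truth <- sample(paste0("C", 1:k), n, replace = TRUE)
    pred <- ifelse(runif(n) < 0.6, truth,
                   sample(paste0("C", 1:k), n, replace = TRUE))
    ev <- evaluateModel(pred, truth)
    nc <- table(factor(truth, levels = sort(unique(truth))))
    expect_equal(accuracy(ev),
                 sum(sensitivity(ev)[names(nc)] * nc) / n,
                 tolerance = 1e-12)
    expect_gte(ev@cramersV, 0)
    expect_lte(ev@cramersV, 1)
  }
})

test_that("five-class evaluation reports one-vs-others pairs per class", {
  set.seed(53)
  lev <- c("B", "T1", "T2", "T3", "T4")
  truth <- rep(lev, each = 20)
  pred <- sample(lev, 100, replace = TRUE)
  ev <- evaluateModel(pred, truth)
  expect_named(sensitivity(ev), lev)
  expect_named(specificity(ev), lev)
  expect_equal(dim(confusionMatrix(ev)), c(5L, 5L))
})
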
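#' Stratified train/test split
#'
#' Splits the windows of a feature matrix into training and test sets,
#' stratified by class so the 75/25 arithmetic is exact (8500 windows from 85
#' subjects give 6375 training and 2125 test vectors). With
#' \code{groupBySubject = TRUE} whole subjects are assigned to one side.
#'
#' @param x a \linkS4class{PainFeatureMatrix}.
#' @param spec a \linkS4class{SplitSpec}.
#' @return list with elements \code{train} and \code{test}
#'   (\linkS4class{PainFeatureMatrix}) and the index vectors \code{trainIdx},
#'   \code{testIdx}.
#' @export
splitData <- function(x, spec = splitSpec()) {
  stopifnot(is(x, "PainFeatureMatrix"))
  labels <- droplevels(classLabels(x))
  set.seed(spec@seed)
  if (spec@groupBySubject) {
    subj <- colData(x)$subject_id
    us <- unique(subj)
    nTr <- round(length(us) * spec@trainFraction)
    trSubj <- us[sample.int(length(us))][seq_len(nTr)]
    trainIdx <- which(subj %in% trSubj)
  } else {
    if (any(table(labels) < 4L))
      stop("stratified split needs at least 4 samples per class")
    trainIdx <- integer(0)
    for (cl in levels(labels)) {
      ix <- which(labels == cl)
      nTr <- round(length(ix) * spec@trainFraction)
      trainIdx <- c(trainIdx, ix[sample.int(length(ix))][seq_len(nTr)])
    }
    trainIdx <- sort(trainIdx)
  }
  testIdx <- setdiff(seq_len(ncol(x)), trainIdx)
  list(train = x[, trainIdx], test = x[, testIdx],
       trainIdx = trainIdx, testIdx = testIdx)
}

#' Exponential grid search for the RBF-SVM
#'
#' Evaluates every (C, gamma) pair of the exponential grids by stratified
#' cross-validated accuracy on the training data, picks the pair with the
#' highest accuracy (ties towards smaller C, then smaller gamma), and refits
#' the model on all training data with that pair.
#'
#' @param x numeric matrix, samples x features.
#' @param labels class labels (>= 2 classes).
#' @param cfg an \linkS4class{SVMConfig}.
#' @param seed RNG seed of the fold assignment.
#' @return list with \code{model} (an \pkg{e1071} svm fit), \code{C},
#'   \code{gamma} and \code{cvAccuracy}.
#' @export
gridSearchTrain <- function(x, labels, cfg = svmConfig(), seed = 1L) {
  labels <- droplevels(factor(labels))
  if (nlevels(labels) < 2L) stop("grid search needs at least 2 classes")
  if (!all(is.finite(x))) stop("non-finite feature values")
  folds <- stratifiedFolds(labels, cfg@cvFolds, seed)
  bestAcc <- -Inf; bestC <- NA_real_; bestG <- NA_real_
  for (C in sort(cfg@cGrid)) {
    for (g in sort(cfg@gammaGrid)) {
      acc <- .cvAccuracy(x, labels, seq_len(ncol(x)), folds,
                         svmClassifier(C, g))
      if (acc > bestAcc) { bestAcc <- acc; bestC <- C; bestG <- g }
    }
  }
  model <- e1071::svm(x = x, y = labels, kernel = "radial", cost = bestC,
                      gamma = bestG, scale = FALSE)
  list(model = model, C = bestC, gamma = bestG, cvAccuracy = bestAcc)
}

#' Association band of a Cramer's V value
#' @param v numeric(1) in [0, 1].
#' @return character(1): negligible, weak, moderate, relatively strong,
#'   strong or very strong.
#' @export
cramersVBand <- function(v) {
  if (is.na(v)) return(NA_character_)
  cuts <- c(0.1, 0.2, 0.4, 0.6, 0.8)
  lab <- c("negligible", "weak", "moderate", "relatively strong", "strong",
           "very strong")
  lab[findInterval(v, cuts) + 1L]
}

#' Cramer's V of a confusion table
#'
#' V = sqrt(chi^2 / (n (min(rows, cols) - 1))) with the Pearson chi-squared
#' statistic of the table; ranges from 0 (independence) to 1 (perfect
#' association). Rows or columns with zero margin are dropped first; a table
#' degenerating below 2 x 2 yields NA.
#'
#' @param confusion numeric matrix of counts.
#' @return numeric(1) in [0, 1], or NA for a degenerate table.
#' @examples
#' cramersV(matrix(c(40, 20, 10, 30), 2))   # 0.4082...
#' @export
cramersV <- function(confusion) {
  tab <- as.matrix(confusion)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) return(NA_real_)
  n <- sum(tab)
  E <- outer(rowSums(tab), colSums(tab)) / n
  chi2 <- sum((tab - E)^2 / E)
  sqrt(chi2 / (n * (min(dim(tab)) - 1L)))
}

#' Evaluate predictions on a test set
#'
#' Builds the predicted-by-true confusion matrix and derives: accuracy
#' (correctly predicted test vectors over all test vectors), per-class
#' sensitivity (correct predictions of a class over all its test vectors) and
#' specificity (correct rejections over all other classes' test vectors,
#' one-vs-others for more than two classes), and Cramer's V with its
#' association band.
#'
#' @param predicted predicted class labels.
#' @param truth true class labels (same length, non-empty).
#' @param task optional task name recorded in the report.
#' @param selected optional character vector of selected features.
#' @param svmParams optional named numeric \code{c(C = , gamma = )}.
#' @param trace optional forward-selection trace data.frame.
#' @return an \linkS4class{EvalReport}.
#' @export
evaluateModel <- function(predicted, truth, task = "", selected = character(0),
                          svmParams = c(C = NA_real_, gamma = NA_real_),
                          trace = data.frame(round = integer(0),
                                             feature = character(0),
                                             cv_accuracy = numeric(0))) {
  if (!length(truth)) stop("empty test set")
  lev <- union(levels(factor(truth)), levels(factor(predicted)))
  predicted <- factor(as.character(predicted), levels = lev)
  truth <- factor(as.character(truth), levels = lev)
  conf <- unclass(table(predicted = predicted, true = truth))
  n <- sum(conf)
  acc <- sum(diag(conf)) / n
  sens <- spec <- stats::setNames(numeric(length(lev)), lev)
  for (i in seq_along(lev)) {
    pos <- sum(conf[, i])
    neg <- n - pos
    sens[i] <- if (pos > 0) conf[i, i] / pos else NA_real_
    spec[i] <- if (neg > 0) sum(conf[-i, -i]) / neg else NA_real_
  }
  v <- cramersV(conf)
  new("EvalReport", task = task, confusion = conf, accuracy = acc,
      sensitivity = sens, specificity = spec, cramersV = v,
      band = cramersVBand(v), selectedFeatures = selected,
      svmParams = svmParams, trace = trace)
}

## Task definitions: classes entering each learning problem.
.TASK_CLASSES <- list(
  B_vs_T1 = c("B", "T1"), B_vs_T2 = c("B", "T2"), B_vs_T3 = c("B", "T3"),
  B_vs_T4 = c("B", "T4"), B_vs_T1_vs_T4 = c("B", "T1", "T4"),
  five_class = c("B", "T1", "T2", "T3", "T4"))

#' Names of the supported classification tasks
#' @return character vector of task identifiers.
#' @export
painTasks <- function() names(.TASK_CLASSES)

## Coarse (C, gamma) pre-tune used to fix the wrapper's inner classifier.
.coarseTune <- function(x, labels, cvFolds = 3L, seed = 1L) {
  folds <- stratifiedFolds(labels, cvFolds, seed)
  bestAcc <- -Inf; best <- c(1, 1 / ncol(x))
  for (C in 2^c(-1, 3, 7)) {
    for (g in 2^c(-7, -3, 1)) {
      acc <- .cvAccuracy(x, labels, seq_len(ncol(x)), folds,
                         svmClassifier(C, g))
      if (acc > bestAcc) { bestAcc <- acc; best <- c(C, g) }
    }
  }
  best
}

#' Run a full classification task
#'
#' The complete learning pipeline for one task on a per-person normalized
#' feature matrix: filter windows to the task's classes, stratified 75/25
#' split, manual pre-selection on the training data (static pruning, then
#' |r| >= 0.95 correlation pruning), SVM-wrapped forward selection (3-fold
#' CV with a coarse-tuned fixed (C, gamma)), exponential grid search on the
#' selected features, and evaluation on the held-out test windows. Test data
#' never influence selection or tuning.
#'
#' @param x a \linkS4class{PainFeatureMatrix} (typically z-normalized per
#'   person).
#' @param task one of [painTasks()].
#' @param svmCfg an \linkS4class{SVMConfig}.
#' @param split a \linkS4class{SplitSpec}.
#' @param corThreshold correlation-pruning threshold (default 0.95).
#' @param seed seed for fold assignments.
#' @return an \linkS4class{EvalReport}.
#' @export
runTask <- function(x, task = "B_vs_T4", svmCfg = svmConfig(),
                    split = splitSpec(), corThreshold = 0.95, seed = 1L) {
  stopifnot(is(x, "PainFeatureMatrix"))
  task <- match.arg(task, painTasks())
  cls <- .TASK_CLASSES[[task]]
  x <- x[, as.character(colData(x)$class_label) %in% cls]
  parts <- splitData(x, split)
  ## manual pre-selection on training data only
  ps <- pruneStatic(parts$train)
  pc <- pruneCorrelated(ps$x, corThreshold)
  feats <- rownames(pc$x)
  trX <- t(assay(pc$x, "features"))
  trY <- droplevels(classLabels(pc$x))
  cg <- .coarseTune(trX, trY, svmCfg@cvFolds, deriveSeed(seed, "coarse"))
  fs <- forwardSelect(trX, trY, classifier = svmClassifier(cg[1], cg[2]),
                      cvFolds = svmCfg@cvFolds,
                      seed = deriveSeed(seed, "select"))
  sel <- if (length(fs@kept)) fs@kept else feats[1L]
  gs <- gridSearchTrain(trX[, sel, drop = FALSE], trY, svmCfg,
                        seed = deriveSeed(seed, "grid"))
  teX <- t(assay(parts$test, "features"))[, sel, drop = FALSE]
  teX[is.na(teX)] <- 0   # rare degenerate test-only values; 0 = subject mean
  teY <- droplevels(classLabels(parts$test))
  pred <- as.character(stats::predict(gs$model, teX))
  evaluateModel(pred, teY, task = task, selected = sel,
                svmParams = c(C = gs$C, gamma = gs$gamma), trace = fs@trace)
}
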
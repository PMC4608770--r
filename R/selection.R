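#' Remove static and degenerate features
#'
#' First stage of the manual pre-selection: drops features that are all-zero,
#' constant across all windows, or that carry the degenerate-value sentinel
#' (NA) for any window - values attributable to a compromised signal or to an
#' extraction rule that is uninterpretable on a particular channel.
#'
#' @param x a \linkS4class{PainFeatureMatrix}.
#' @return list with elements \code{x} (pruned matrix) and \code{dropped}
#'   (character vector of removed feature names).
#' @export
pruneStatic <- function(x) {
  stopifnot(is(x, "PainFeatureMatrix"))
  vals <- assay(x, "features")
  sg <- apply(vals, 1L, stats::sd)
  bad <- apply(vals, 1L, anyNA) | is.na(sg) | sg == 0
  if (!is.null(rowData(x)$static)) bad <- bad | rowData(x)$static
  list(x = x[!bad, ], dropped = rownames(vals)[bad])
}

#' Remove highly correlated features
#'
#' Second stage of the manual pre-selection: a greedy scan in canonical
#' feature order drops every feature whose absolute Pearson correlation with
#' an already-retained feature reaches the threshold (0.95 by default),
#' preventing classification of redundant information. The earlier feature of
#' a correlated pair is kept.
#'
#' @param x a \linkS4class{PainFeatureMatrix}.
#' @param threshold absolute-correlation cutoff (default 0.95).
#' @return list with elements \code{x} (pruned matrix) and \code{dropped}
#'   (data.frame with columns \code{dropped}, \code{kept_partner}, \code{r}).
#' @export
pruneCorrelated <- function(x, threshold = 0.95) {
  stopifnot(is(x, "PainFeatureMatrix"))
  vals <- assay(x, "features")
  p <- nrow(vals)
  rec <- data.frame(dropped = character(0), kept_partner = character(0),
                    r = numeric(0))
  if (p < 2L) return(list(x = x, dropped = rec))
  cm <- suppressWarnings(stats::cor(t(vals)))
  keep <- logical(p)
  for (j in seq_len(p)) {
    hits <- which(keep & abs(cm[j, ]) >= threshold & seq_len(p) < j)
    if (length(hits)) {
      k <- hits[1L]
      rec <- rbind(rec, data.frame(dropped = rownames(vals)[j],
                                   kept_partner = rownames(vals)[k],
                                   r = cm[j, k]))
    } else keep[j] <- TRUE
  }
  list(x = x[keep, ], dropped = rec)
}

#' RBF-SVM classifier factory
#'
#' Returns a closure \code{function(trainX, trainY, testX)} fitting an
#' RBF-kernel SVM (one-vs-one for more than two classes) and returning test
#' predictions; the plug-in classifier used by [forwardSelect()].
#'
#' @param C misclassification cost.
#' @param gamma kernel radius; default 1/ncol(trainX).
#' @return a classifier closure.
#' @export
svmClassifier <- function(C = 1, gamma = NULL) {
  function(trainX, trainY, testX) {
    g <- if (is.null(gamma)) 1 / ncol(trainX) else gamma
    fit <- e1071::svm(x = trainX, y = factor(trainY), kernel = "radial",
                      cost = C, gamma = g, scale = FALSE)
    as.character(stats::predict(fit, testX))
  }
}

## Pooled cross-validated accuracy of a feature subset.
.cvAccuracy <- function(x, labels, cols, folds, classifier) {
  correct <- 0L
  for (f in sort(unique(folds))) {
    tr <- folds != f
    pred <- classifier(x[tr, cols, drop = FALSE], labels[tr],
                      x[!tr, cols, drop = FALSE])
    correct <- correct + sum(pred == as.character(labels[!tr]))
  }
  correct / length(labels)
}

#' Wrapper forward feature selection
#'
#' Starts from the empty feature set; each round scores every remaining
#' candidate by the cross-validated classification accuracy of the current
#' set plus that candidate, adds the best one (ties broken towards the lowest
#' column index), and stops as soon as the best candidate no longer strictly
#' increases the accuracy.
#'
#' @param x numeric matrix, samples x features (or a
#'   \linkS4class{PainFeatureMatrix}, transposed internally).
#' @param labels class labels, one per sample (>= 2 classes).
#' @param classifier classifier closure as returned by [svmClassifier()].
#' @param cvFolds stratified cross-validation folds (default 3).
#' @param seed RNG seed of the fold assignment.
#' @param maxRounds safety cap on the number of selection rounds.
#' @return a \linkS4class{SelectionResult}; \code{kept} holds the selected
#'   features in selection order, \code{trace} one row per accepted round.
#' @export
forwardSelect <- function(x, labels, classifier = svmClassifier(),
                          cvFolds = 3L, seed = 1L, maxRounds = 50L) {
  if (is(x, "PainFeatureMatrix")) {
    labels <- classLabels(x)
    x <- t(assay(x, "features"))
  }
  labels <- droplevels(factor(labels))
  if (nlevels(labels) < 2L) stop("forward selection needs at least 2 classes")
  if (ncol(x) < 2L) stop("forward selection needs at least 2 candidate features")
  folds <- stratifiedFolds(labels, cvFolds, seed)
  sel <- integer(0)
  bestAcc <- 0
  trace <- data.frame(round = integer(0), feature = character(0),
                      cv_accuracy = numeric(0))
  cand <- seq_len(ncol(x))
  round <- 0L
  while (length(cand) && round < maxRounds) {
    round <- round + 1L
    accs <- vapply(cand, function(j)
      .cvAccuracy(x, labels, c(sel, j), folds, classifier), numeric(1))
    best <- which.max(accs)   # first max = lowest column index on ties
    if (accs[best] <= bestAcc) break
    bestAcc <- accs[best]
    sel <- c(sel, cand[best])
    trace <- rbind(trace, data.frame(round = round,
                                     feature = colnames(x)[cand[best]],
                                     cv_accuracy = bestAcc))
    cand <- cand[-best]
  }
  new("SelectionResult", kept = colnames(x)[sel],
      droppedStatic = character(0),
      droppedCorrelated = data.frame(dropped = character(0),
                                     kept_partner = character(0),
                                     r = numeric(0)),
      trace = trace)
}
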
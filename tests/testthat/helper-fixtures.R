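## Small fixtures built in code.

## A reduced simulator configuration that runs in seconds.
tinySimConfig <- function(...) {
  simConfig(nSubjects = 2L, repsPerLevel = 3L, nBaseline = 3L, seed = 42L, ...)
}

## A five-channel LabeledWindowSet with synthetic content, cheap enough for
## extractor structure tests: band-limited noise EMG, drifting SCL, and beat
## times on a regular 800 ms grid.
makeWindowSet <- function(nWindows = 10L, fs = 512, windowS = 5.5,
                          seed = 7L, roles = c("emg_zyg", "emg_cor",
                                               "emg_tra", "scl", "ecg")) {
  set.seed(seed)
  nSeg <- as.integer(round(windowS * fs))
  labels <- factor(rep(c("B", "T1", "T2", "T3", "T4"),
                       length.out = nWindows),
                   levels = c("B", "T1", "T2", "T3", "T4"))
  onsets <- seq(0, by = windowS + 1, length.out = nWindows)
  chans <- lapply(roles, function(role) {
    m <- matrix(rnorm(nSeg * nWindows), nSeg, nWindows)
    if (role == "scl") m <- 5 + 0.1 * apply(m, 2, cumsum) / sqrt(nSeg)
    m
  })
  names(chans) <- roles
  dur <- max(onsets) + windowS
  new("LabeledWindowSet", subjectId = "SYN1", fs = fs, windowS = windowS,
      labels = labels, onsets = onsets, channels = chans,
      beatTimes = seq(0.1, dur, by = 0.8))
}

## A feature matrix with random content for split/selection mechanics.
makeRandomFeatureMatrix <- function(nFeat = 12L, nSubjects = 4L,
                                    perClass = 5L, seed = 99L) {
  set.seed(seed)
  labels <- rep(rep(c("B", "T1", "T2", "T3", "T4"), each = perClass),
                nSubjects)
  subjects <- rep(sprintf("S%02d", seq_len(nSubjects)),
                  each = perClass * 5L)
  vals <- matrix(rnorm(nFeat * length(labels)), nFeat,
                 dimnames = list(sprintf("F%02d", seq_len(nFeat)), NULL))
  painFeatureMatrix(vals, subjects, labels)
}

## Nearest-centroid stub classifier for wrapper-selection oracle tests.
centroidClassifier <- function(trainX, trainY, testX) {
  trainY <- as.character(trainY)
  cents <- vapply(unique(trainY), function(cl)
    colMeans(trainX[trainY == cl, , drop = FALSE]), numeric(ncol(trainX)))
  cents <- matrix(cents, ncol = length(unique(trainY)),
                  dimnames = list(NULL, unique(trainY)))
  d <- vapply(colnames(cents), function(cl)
    rowSums((testX - matrix(cents[, cl], nrow(testX), ncol(testX),
                            byrow = TRUE))^2), numeric(nrow(testX)))
  colnames(cents)[max.col(-matrix(d, nrow(testX)))]
}
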
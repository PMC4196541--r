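#' Train a two-class linear discriminant
#'
#' Classical LDA: weights are the pooled-covariance inverse times the class
#' mean difference, and the bias places the decision boundary at the midpoint
#' of the class means. The pooled covariance is ridge-stabilized by adding
#' `1e-6 * trace/dim` to its diagonal, so near-singular small-sample fits
#' never crash. A positive decision score `w'x + b` predicts the first class
#' in sorted label order.
#'
#' @param X trials x features numeric matrix.
#' @param y per-trial labels with exactly two distinct values.
#' @return list with `weights`, `bias`, and `classes` (sorted label pair)
#' @export
trainLDA <- function(X, y) {
  X <- as.matrix(X)
  classes <- sort(unique(as.character(y)))
  if (length(classes) != 2L)
    stop("exactly two classes required", call. = FALSE)
  g1 <- y == classes[1]
  n1 <- sum(g1); n2 <- sum(!g1)
  if (n1 < 2L || n2 < 2L)
    stop("both classes need at least two trials", call. = FALSE)
  mu1 <- colMeans(X[g1, , drop = FALSE])
  mu2 <- colMeans(X[!g1, , drop = FALSE])
  c1 <- sweep(X[g1, , drop = FALSE], 2L, mu1)
  c2 <- sweep(X[!g1, , drop = FALSE], 2L, mu2)
  Sp <- (crossprod(c1) + crossprod(c2)) / (n1 + n2 - 2L)
  p <- ncol(X)
  Sp <- Sp + diag(1e-6 * sum(diag(Sp)) / p + 1e-12, p)
  w <- solve(Sp, mu1 - mu2)
  list(weights = as.numeric(w),
       bias = -sum(w * (mu1 + mu2) / 2),
       classes = classes)
}

# decision scores of one trial's full feature time course (nsel x T matrix)
.ldaScores <- function(model, featT) {
  colSums(model$weights * featT) + model$bias
}

# calibration workhorse operating on a precomputed feature array.
# vals: trials x features x samples (selected trials only); labels: their labels.
.calibrateCore <- function(vals, index, labels, fs, validFrom,
                           windowRange = c(4, 8), nWindows = 8L,
                           featureSelection = c("per_derivation", "global_single")) {
  featureSelection <- match.arg(featureSelection)
  classes <- sort(unique(labels))
  stopifnot(length(classes) == 2L)
  n <- length(labels)

  # 1) band selection
  evalIdx <- .windowIdx(windowRange[1], windowRange[2], fs)
  if (featureSelection == "per_derivation") {
    selIdx <- integer(0); selFisher <- numeric(0)
    for (d in unique(index$derivationIndex)) {
      cols <- which(index$derivationIndex == d)
      sb <- selectBestBand(vals[, cols, , drop = FALSE], labels, fs, windowRange)
      selIdx <- c(selIdx, cols[sb$band])
      selFisher <- c(selFisher, sb$score)
    }
  } else {
    wm <- .windowMeans(vals, evalIdx)
    g1 <- labels == classes[1]
    sc <- vapply(seq_len(ncol(wm)), function(f) fisherScore(wm[g1, f], wm[!g1, f]), 0)
    selIdx <- which.max(sc)
    selFisher <- sc[selIdx]
  }
  sel <- vals[, selIdx, , drop = FALSE]
  nSel <- length(selIdx)

  # 2) LooCV over the eight adjacent 0.5 s training windows
  winStarts <- seq(windowRange[1], windowRange[2] - 0.5, length.out = nWindows)
  winScores <- numeric(nWindows)
  validMask <- !is.na(sel[1, 1, ])
  medIdx <- evalIdx[validMask[evalIdx]]
  for (k in seq_len(nWindows)) {
    widx <- .windowIdx(winStarts[k], winStarts[k] + 0.5, fs)
    Xw <- .windowMeans(sel, widx)
    correct <- matrix(NA, n, length(medIdx))
    for (j in seq_len(n)) {
      m <- trainLDA(Xw[-j, , drop = FALSE], labels[-j])
      featT <- matrix(sel[j, , medIdx], nrow = nSel)
      pred <- ifelse(.ldaScores(m, featT) > 0, m$classes[1], m$classes[2])
      correct[j, ] <- pred == labels[j]
    }
    winScores[k] <- median(colMeans(correct))
  }
  best <- which.max(winScores)   # earliest window on ties

  # 3) final model on all trials with the chosen window
  widx <- .windowIdx(winStarts[best], winStarts[best] + 0.5, fs)
  finalModel <- trainLDA(.windowMeans(sel, widx), labels)

  selectedFeatures <- data.frame(derivation = index$derivation[selIdx],
                                 band = index$band[selIdx])
  clf <- new("CalibratedClassifier",
             classPair = finalModel$classes,
             selectedFeatures = selectedFeatures,
             trainWindow = c(winStarts[best], winStarts[best] + 0.5),
             weights = finalModel$weights, bias = finalModel$bias,
             loocvMedianAccuracy = winScores[best],
             bestFeatureFisher = max(selFisher))
  report <- list(windowStarts = winStarts, windowAccuracies = winScores,
                 chosenWindow = best, classPair = finalModel$classes,
                 selectedFeatures = selectedFeatures,
                 featureFisher = selFisher,
                 loocvMedianAccuracy = winScores[best],
                 bestFeatureFisher = max(selFisher))
  list(classifier = clf, report = report)
}

#' Calibrate a pairwise classifier on an epoched session
#'
#' Full calibration procedure for two classes: per derivation, the most
#' separable band is chosen by Fisher score over the 4-8 s window; the 4-8 s
#' interval is split into eight adjacent 0.5 s training windows and each is
#' scored by leave-one-out cross-validation (training on window-averaged
#' features of held-in trials, applying the discriminant to the held-out
#' trial's full feature time course, pooling per-timepoint correctness
#' across folds and taking the median over 4-8 s); the window with the
#' highest median accuracy (earliest on ties) trains the final LDA on all
#' trials.
#'
#' @param session an [EpochedSession-class]; only artifact-free trials of
#'   exactly two classes are used, each class needing at least two.
#' @param derivations list of [BipolarDerivation-class].
#' @param bands band-edge matrix (default [defaultBands()]).
#' @param avgWindow band-power averaging window in seconds.
#' @param windowRange analysis window (default `c(4, 8)` seconds).
#' @param featureSelection `"per_derivation"` (one feature per derivation,
#'   default) or `"global_single"` (one feature overall).
#' @return list with `classifier` (a [CalibratedClassifier-class]) and
#'   `report` (per-window LooCV accuracies, chosen window, feature table)
#' @export
calibrate <- function(session, derivations, bands = defaultBands(),
                      avgWindow = 1, windowRange = c(4, 8),
                      featureSelection = "per_derivation") {
  keep <- which(!session@artifactFlags)
  labels <- session@labels[keep]
  classes <- sort(unique(labels))
  if (length(classes) != 2L)
    stop("calibrate() needs trials of exactly two classes", call. = FALSE)
  if (any(table(factor(labels, classes)) < 2L))
    stop("calibration deferred: both classes need at least two artifact-free trials",
         call. = FALSE)
  sub <- session@epochs[keep, , , drop = FALSE]
  feats <- computeFeatures(
    epochedSession(sub, labels, session@timing, session@channelLabels),
    derivations, bands, avgWindow)
  .calibrateCore(feats$values, feats$index, labels, session@timing@fs,
                 feats$validFrom, windowRange,
                 featureSelection = featureSelection)
}

# pair selection given precomputed features of all candidate trials
.autoSelectCore <- function(vals, index, labels, fs, validFrom,
                            windowRange = c(4, 8),
                            featureSelection = "per_derivation") {
  classes <- sort(unique(labels))
  pairs <- combn(classes, 2L)
  cand <- vector("list", ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    sel <- labels %in% pairs[, p]
    cand[[p]] <- .calibrateCore(vals[sel, , , drop = FALSE], index, labels[sel],
                                fs, validFrom, windowRange,
                                featureSelection = featureSelection)
  }
  acc <- vapply(cand, function(x) x$classifier@loocvMedianAccuracy, 0)
  fish <- vapply(cand, function(x) x$classifier@bestFeatureFisher, 0)
  bestAcc <- max(acc)
  tied <- which(acc == bestAcc)
  best <- tied[which.max(fish[tied])]   # Fisher tie-break, then first (lexicographic)
  list(pair = pairs[, best], classifier = cand[[best]]$classifier,
       report = cand[[best]]$report,
       candidates = data.frame(classA = pairs[1, ], classB = pairs[2, ],
                               loocvMedianAccuracy = acc,
                               bestFeatureFisher = fish),
       reports = lapply(cand, `[[`, "report"))
}

#' Automatic class-pair selection among four classes
#'
#' Runs the regular calibration for every one of the six binary combinations
#' of the four classes and returns the pair with the highest LooCV median
#' accuracy. Exact accuracy ties go to the pair whose best feature has the
#' higher Fisher separability; any remaining tie is broken lexicographically.
#'
#' @inheritParams calibrate
#' @return list with `pair`, `classifier`, `report`, and `candidates` (a
#'   data.frame of all six pairs' scores)
#' @export
autoSelectClasses <- function(session, derivations, bands = defaultBands(),
                              avgWindow = 1, windowRange = c(4, 8),
                              featureSelection = "per_derivation") {
  keep <- which(!session@artifactFlags)
  labels <- session@labels[keep]
  classes <- sort(unique(labels))
  if (length(classes) != 4L)
    stop("automatic class selection needs trials of exactly four classes",
         call. = FALSE)
  if (any(table(factor(labels, classes)) < 2L))
    stop("calibration deferred: every class needs at least two artifact-free trials",
         call. = FALSE)
  sub <- session@epochs[keep, , , drop = FALSE]
  feats <- computeFeatures(
    epochedSession(sub, labels, session@timing, session@channelLabels),
    derivations, bands, avgWindow)
  .autoSelectCore(feats$values, feats$index, labels, session@timing@fs,
                  feats$validFrom, windowRange, featureSelection)
}
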
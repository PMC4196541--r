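#' Per-timepoint accuracy time course of an adaptive run
#'
#' `accuracy(t)` is the fraction of evaluated trials whose prediction at
#' timepoint `t` equals the true label, over the timepoints that are valid
#' (past the feature warm-up) in all evaluated trials.
#'
#' @param result an [AdaptiveSessionResult-class] with at least one evaluated
#'   trial.
#' @return list of class `"AccuracyTimecourse"` with `times` (seconds),
#'   `accuracy` (fraction per timepoint) and `nTrials`
#' @export
accuracyTimecourse <- function(result) {
  ev <- which(result@trialLog$evaluated)
  if (!length(ev))
    stop("no evaluated trials: the session never produced predictions", call. = FALSE)
  truth <- match(result@trialLog$label[ev], result@selectedPair)
  pred <- result@predictions
  stopifnot(nrow(pred) == length(ev))
  correct <- sweep(pred, 1L, truth, "==")
  valid <- colSums(is.na(pred)) == 0L
  fs <- result@timing@fs
  times <- (seq_len(ncol(pred)) - 1L) / fs
  structure(list(times = times[valid],
                 accuracy = colMeans(correct[, valid, drop = FALSE]),
                 nTrials = length(ev)),
            class = "AccuracyTimecourse")
}

.windowAccuracy <- function(tc, window, fun) {
  sel <- tc$times >= window[1] & tc$times < window[2]
  if (!any(sel))
    stop("window does not overlap the accuracy time course", call. = FALSE)
  fun(tc$accuracy[sel])
}

#' Median and peak accuracy within the analysis window
#'
#' The median accuracy between seconds 4 and 8 is the robust measure used
#' for model selection and channel/class ranking; the peak accuracy within
#' the same window is the final performance measure. Peak is always at least
#' the median.
#'
#' @param tc an `"AccuracyTimecourse"` from [accuracyTimecourse()].
#' @param window numeric length-2, `[start, end)` seconds (default `c(4, 8)`).
#' @return fraction in `[0, 1]`
#' @export
medianAccuracy <- function(tc, window = c(4, 8)) .windowAccuracy(tc, window, median)

#' @rdname medianAccuracy
#' @export
peakAccuracy <- function(tc, window = c(4, 8)) .windowAccuracy(tc, window, max)

#' Exact binomial chance-level bound
#'
#' Smallest accuracy `k/nTrials` whose one-sided binomial tail probability
#' under guessing (success probability `1/nClasses`) is at most `alpha`.
#' Exact tail, no normal approximation. With 60 trials and two classes at
#' `alpha = 0.01` the bound is 40/60 (about 66.7%).
#'
#' @param nTrials number of evaluated trials (>= 1).
#' @param nClasses number of classes (>= 2).
#' @param alpha significance level in (0, 1).
#' @return accuracy bound as a fraction
#' @examples
#' chanceLevel(60, 2, 0.01)  # 0.6667
#' @export
chanceLevel <- function(nTrials, nClasses = 2L, alpha = 0.01) {
  stopifnot(nTrials >= 1L, nClasses >= 2L, alpha > 0, alpha < 1)
  p <- 1 / nClasses
  k <- 0:nTrials
  tail <- pbinom(k - 1L, nTrials, p, lower.tail = FALSE)  # P(X >= k)
  min(k[tail <= alpha]) / nTrials
}

#' Channel/class ranking sweep
#'
#' Simulates the single-derivation, two-class (mini) adaptive configuration
#' on every combination of one bipolar derivation and one class pair, and
#' records the median accuracy of each run. Cells whose run never calibrated
#' (or never evaluated a trial) are recorded as `NA` and excluded from the
#' ranking medians.
#'
#' @param session an [EpochedSession-class] covering all swept classes.
#' @param derivations list of [BipolarDerivation-class] to sweep.
#' @param classes class labels to pair up; defaults to all classes in the
#'   session.
#' @param ... further arguments passed to [adaptiveConfig()] (e.g.
#'   `rejection`, `nInitTpc`).
#' @return a `"SweepResult"`: data.frame with columns `derivation`, `classA`,
#'   `classB`, `medianAccuracy`, carrying the derivation list as attribute
#'   `derivations`
#' @export
runChannelSweep <- function(session, derivations, classes = NULL, ...) {
  if (is.null(classes)) classes <- sort(unique(session@labels))
  pairs <- combn(sort(classes), 2L)
  cells <- expand.grid(derivation = seq_along(derivations),
                       pair = seq_len(ncol(pairs)))
  out <- data.frame(derivation = character(nrow(cells)),
                    classA = character(nrow(cells)),
                    classB = character(nrow(cells)),
                    medianAccuracy = NA_real_, stringsAsFactors = FALSE)
  for (r in seq_len(nrow(cells))) {
    d <- cells$derivation[r]; p <- cells$pair[r]
    cfg <- adaptiveConfig("mini", derivations[d], pairs[, p], ...)
    res <- runSession(session, cfg)
    acc <- if (res@calibrated && any(res@trialLog$evaluated))
      medianAccuracy(accuracyTimecourse(res)) else NA_real_
    out$derivation[r] <- derivationLabel(derivations[[d]])
    out$classA[r] <- pairs[1, p]
    out$classB[r] <- pairs[2, p]
    out$medianAccuracy[r] <- acc
  }
  attr(out, "derivations") <- derivations
  class(out) <- c("SweepResult", class(out))
  out
}

# per-derivation ranking statistic over class-pair cells
.derivationScores <- function(sweep, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  f <- if (stat == "median") median else mean
  tapply(sweep$medianAccuracy, sweep$derivation, f, na.rm = TRUE)
}

#' Greedy selection of non-overlapping derivations
#'
#' Ranks derivations by the median (over class pairs) of their sweep cells,
#' walks the ranking best-first and keeps each derivation only if it overlaps
#' no previously kept one, then returns the first `k` kept. Ties in the
#' ranking are broken lexicographically by label for determinism.
#'
#' @param sweep a `"SweepResult"` from [runChannelSweep()].
#' @param k number of derivations to select (default 3).
#' @param stat ranking statistic over a derivation's cells, `"median"`
#'   (default) or `"mean"`.
#' @return list with `selected` (list of [BipolarDerivation-class], best
#'   first) and `trace` (data.frame of the greedy walk: `derivation`,
#'   `score`, `action`)
#' @export
selectChannels <- function(sweep, k = 3L, stat = "median") {
  derivations <- attr(sweep, "derivations")
  labs <- vapply(derivations, derivationLabel, "")
  scores <- .derivationScores(sweep, stat)[labs]
  ord <- order(-scores, labs)
  kept <- list()
  trace <- data.frame(derivation = character(0), score = numeric(0),
                      action = character(0))
  for (i in ord) {
    if (is.na(scores[i])) {
      trace <- rbind(trace, data.frame(derivation = labs[i], score = NA_real_,
                                       action = "skipped:no-result"))
      next
    }
    overlaps <- any(vapply(kept, derivationsOverlap, NA, d2 = derivations[[i]]))
    action <- if (length(kept) >= k) "skipped:full"
              else if (isTRUE(overlaps)) "skipped:overlap"
              else "kept"
    trace <- rbind(trace, data.frame(derivation = labs[i],
                                     score = unname(scores[i]), action = action))
    if (action == "kept") kept[[length(kept) + 1L]] <- derivations[[i]]
    if (length(kept) == k) break
  }
  if (length(kept) < k)
    warning(sprintf("only %d non-overlapping derivations available (requested %d)",
                    length(kept), k))
  list(selected = kept, trace = trace)
}

#' Select the best-performing classes from a sweep
#'
#' Restricts the sweep to the selected derivations, scores each class by the
#' mean of all cells of pairs containing it (averaged over those derivations
#' and pairs), and returns the top `m` classes. Ties are broken
#' lexicographically.
#'
#' @param sweep a `"SweepResult"`.
#' @param derivations derivations to restrict to (e.g. the output of
#'   [selectChannels()]); `NULL` uses all.
#' @param m number of classes to keep (default 4).
#' @return character vector of the selected classes, plus attribute
#'   `scores` with all class scores
#' @export
selectClasses <- function(sweep, derivations = NULL, m = 4L) {
  sub <- sweep
  if (!is.null(derivations)) {
    labs <- vapply(derivations, derivationLabel, "")
    sub <- sweep[sweep$derivation %in% labs, , drop = FALSE]
  }
  classes <- sort(unique(c(sub$classA, sub$classB)))
  scores <- vapply(classes, function(cl)
    mean(sub$medianAccuracy[sub$classA == cl | sub$classB == cl], na.rm = TRUE), 0)
  ord <- order(-scores, classes)
  sel <- classes[ord[seq_len(min(m, length(classes)))]]
  structure(sel, scores = setNames(scores, classes))
}

#' Fisher-separability map over derivations and bands
#'
#' For every derivation x band cell, averages the Fisher score of
#' window-averaged imagery features over all class pairs passing the filter,
#' after outlier rejection. Filters follow the usual grouping of mental
#' tasks into motor (`motorClasses`) and non-motor: `"MTvsMT"` keeps
#' motor/motor pairs, `"MTvsnM"` motor/non-motor, `"nMvsnM"`
#' non-motor/non-motor, `"any"` all pairs.
#'
#' @param session an [EpochedSession-class].
#' @param derivations list of [BipolarDerivation-class].
#' @param bands band-edge matrix.
#' @param filter pair filter (see above).
#' @param motorClasses labels counted as motor imagery.
#' @param rejection a [RejectionConfig-class], applied before scoring;
#'   `NULL` skips rejection (e.g. if flags are already set).
#' @param window analysis window in seconds.
#' @param avgWindow band-power averaging window in seconds.
#' @return numeric matrix derivations x bands of mean Fisher scores
#' @export
separabilityMap <- function(session, derivations, bands = defaultBands(),
                            filter = c("any", "MTvsMT", "MTvsnM", "nMvsnM"),
                            motorClasses = c("Feet", "Hand"),
                            rejection = rejectionConfig(), window = c(4, 8),
                            avgWindow = 1) {
  filter <- match.arg(filter)
  if (!is.null(rejection))
    session <- runOutlierPipeline(session, rejection, derivations)
  keep <- which(!session@artifactFlags)
  labels <- session@labels[keep]
  classes <- sort(unique(labels))
  pairs <- combn(classes, 2L)
  isMotor <- function(cl) cl %in% motorClasses
  passes <- vapply(seq_len(ncol(pairs)), function(p) {
    m1 <- isMotor(pairs[1, p]); m2 <- isMotor(pairs[2, p])
    switch(filter,
           any = TRUE,
           MTvsMT = m1 && m2,
           MTvsnM = xor(m1, m2),
           nMvsnM = !m1 && !m2)
  }, NA)
  if (!any(passes))
    stop("no class pair passes the filter", call. = FALSE)
  pairs <- pairs[, passes, drop = FALSE]

  sub <- epochedSession(session@epochs[keep, , , drop = FALSE], labels,
                        session@timing, session@channelLabels)
  feats <- computeFeatures(sub, derivations, bands, avgWindow)
  idx <- .windowIdx(window[1], window[2], session@timing@fs)
  wm <- .windowMeans(feats$values, idx)   # trials x features
  nD <- length(derivations); nB <- nrow(bands)
  map <- matrix(0, nD, nB,
                dimnames = list(vapply(derivations, derivationLabel, ""),
                                rownames(bands)))
  for (f in seq_len(ncol(wm))) {
    d <- feats$index$derivationIndex[f]; b <- feats$index$band[f]
    sc <- vapply(seq_len(ncol(pairs)), function(p) {
      g1 <- labels == pairs[1, p]; g2 <- labels == pairs[2, p]
      fisherScore(wm[g1, f], wm[g2, f])
    }, 0)
    map[d, b] <- mean(sc)
  }
  map
}
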
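#' Adaptive BCI configuration
#'
#' Configuration of one simulated adaptive session. `mini` uses a single
#' bipolar derivation and two classes; `smr` uses three derivations and the
#' two motor-imagery classes; `auto` uses three derivations and four classes
#' among which the initial calibration selects the best pair.
#'
#' @param mode `"mini"`, `"smr"` or `"auto"`.
#' @param derivations list of [BipolarDerivation-class] (1 for mini,
#'   typically 3 for smr/auto).
#' @param classes class labels in scope (2 for mini/smr, 4 for auto).
#' @param nInitTpc artifact-free trials per class collected before the
#'   initial calibration (default 7).
#' @param nUpdateTpc new artifact-free trials per class between
#'   recalibrations (default 7).
#' @param bands band-edge matrix.
#' @param timing a [TrialTiming-class] (used for validation and defaults).
#' @param rejection a [RejectionConfig-class].
#' @param avgWindow band-power averaging window in seconds.
#' @param windowRange analysis window in seconds.
#' @param featureSelection `"per_derivation"` or `"global_single"`.
#' @param updateRule `"per_class"` (every in-scope class must accumulate
#'   `nUpdateTpc` new trials, default) or `"total"` (`nUpdateTpc` new trials
#'   overall).
#' @return a list of class `"AdaptiveConfig"`
#' @export
adaptiveConfig <- function(mode = c("mini", "smr", "auto"), derivations, classes,
                           nInitTpc = 7L, nUpdateTpc = 7L, bands = defaultBands(),
                           timing = trialTiming(), rejection = rejectionConfig(),
                           avgWindow = 1, windowRange = c(4, 8),
                           featureSelection = "per_derivation",
                           updateRule = c("per_class", "total")) {
  mode <- match.arg(mode)
  updateRule <- match.arg(updateRule)
  nD <- length(derivations); nC <- length(classes)
  if (mode == "mini" && nD != 1L)
    stop("mini mode uses exactly one bipolar derivation", call. = FALSE)
  if (mode %in% c("mini", "smr") && nC != 2L)
    stop(sprintf("%s mode needs exactly two classes, got %d", mode, nC), call. = FALSE)
  if (mode == "auto" && nC != 4L)
    stop(sprintf("auto mode needs exactly four classes, got %d", nC), call. = FALSE)
  if (nInitTpc < 2L) stop("nInitTpc must be >= 2", call. = FALSE)
  if (nUpdateTpc < 1L) stop("nUpdateTpc must be >= 1", call. = FALSE)
  structure(list(mode = mode, derivations = derivations,
                 classes = as.character(classes),
                 nInitTpc = as.integer(nInitTpc), nUpdateTpc = as.integer(nUpdateTpc),
                 bands = bands, timing = timing, rejection = rejection,
                 avgWindow = avgWindow, windowRange = windowRange,
                 featureSelection = featureSelection, updateRule = updateRule),
            class = "AdaptiveConfig")
}

# per-trial summaries used by the prequential outlier screening and the
# calibration feature array, computed once (all quantities are per-trial and
# causal, so precomputing leaks nothing across trials).
.engineFeatures <- function(session, cfg, needed) {
  tm <- session@timing; fs <- tm@fs
  relaxIdx <- .windowIdx(tm@relaxStart, tm@relaxEnd, fs)
  imagIdx <- .windowIdx(tm@cueOnset, tm@imageryEndAnalysis, fs)
  derivations <- cfg$derivations
  bands <- cfg$bands
  nT <- nTrials(session); nD <- length(derivations); nB <- nrow(bands)
  nS <- dim(session@epochs)[3L]
  w <- round(cfg$avgWindow * fs)

  dsig <- derivationSignals(session, derivations)
  vals <- array(NA_real_, c(nT, nD * nB, nS))
  bp <- list(relax = matrix(NA_real_, nT, nD * nB),
             imagery = matrix(NA_real_, nT, nD * nB))
  for (d in seq_len(nD)) {
    for (b in seq_len(nB)) {
      bf <- .butterBand(bands[b, 1], bands[b, 2], fs)
      f <- (d - 1L) * nB + b
      for (tr in needed) {
        filt <- as.numeric(signal::filter(bf, dsig[tr, d, ]))
        sq <- filt^2
        vals[tr, f, ] <- log(pmax(.trailingMean(sq, w), 1e-10))
        bp$relax[tr, f] <- log(pmax(mean(sq[relaxIdx]), 1e-10))
        bp$imagery[tr, f] <- log(pmax(mean(sq[imagIdx]), 1e-10))
      }
    }
  }
  index <- data.frame(
    derivation = rep(vapply(derivations, derivationLabel, ""), each = nB),
    derivationIndex = rep(seq_len(nD), each = nB),
    band = rep.int(seq_len(nB), nD))

  rej <- cfg$rejection
  elec <- unique(unlist(lapply(derivations, function(d) c(d@anode, d@cathode))))
  elec <- setdiff(elec, rej@excludeChannels)
  chIdx <- match(elec, session@channelLabels)
  if (anyNA(chIdx))
    stop("derivation electrodes missing from session channels", call. = FALSE)
  nCh <- length(chIdx)
  nBins <- rej@nBins
  # fixed histogram support: the amplitude phase bounds surviving samples
  edges <- seq(-rej@amplitudeLimit, rej@amplitudeLimit, length.out = nBins + 1L)
  ampBad <- kurt <- counts <- nSamp <- list()
  for (segName in c("relax", "imagery")) {
    idx <- if (segName == "relax") relaxIdx else imagIdx
    ampBad[[segName]] <- rep(NA, nT)
    kurt[[segName]] <- matrix(NA_real_, nT, nCh)
    counts[[segName]] <- array(NA_real_, c(nT, nCh, nBins))
    nSamp[[segName]] <- length(idx)
    for (tr in needed) {
      seg <- session@epochs[tr, chIdx, idx, drop = TRUE]
      if (is.null(dim(seg))) seg <- matrix(seg, nrow = 1L)
      ampBad[[segName]][tr] <- any(abs(seg) > rej@amplitudeLimit)
      for (c in seq_len(nCh)) {
        kurt[[segName]][tr, c] <- e1071::kurtosis(seg[c, ], type = 1L)
        bin <- findInterval(seg[c, ], edges, rightmost.closed = TRUE,
                            all.inside = TRUE)
        counts[[segName]][tr, c, ] <- tabulate(bin, nbins = nBins)
      }
    }
  }
  list(vals = vals, index = index, validFrom = cfg$avgWindow, bp = bp,
       ampBad = ampBad, kurt = kurt, counts = counts, nSamp = nSamp,
       binWidth = diff(edges))
}

# is trial i an outlier relative to pool `grp` (arrival indices, same segment
# grouping semantics as the batch pipeline)? Returns character reasons.
.screenTrial <- function(pre, i, relaxPool, imagPool, rej) {
  reasons <- character(0)
  for (segName in c("relax", "imagery")) {
    if (pre$ampBad[[segName]][i])
      reasons <- c(reasons, paste0("amplitude:", segName))
  }
  if (length(reasons)) return(reasons)
  for (segName in c("relax", "imagery")) {
    grp <- c(if (segName == "relax") relaxPool else imagPool, i)
    if (length(grp) < 3L) next
    me <- length(grp)   # position of trial i
    # kurtosis + probability measures
    K <- pre$kurt[[segName]][grp, , drop = FALSE]
    flagged <- FALSE
    for (c in seq_len(ncol(K))) {
      if (abs(.zscore(K[, c])[me]) > rej@zLimit) { flagged <- TRUE; break }
      C <- pre$counts[[segName]][grp, c, , drop = TRUE]
      if (is.null(dim(C))) C <- matrix(C, nrow = length(grp))
      pooled <- .smoothCounts(colSums(C))
      dens <- pooled / (sum(pooled) * pre$binWidth)
      m <- as.numeric(C %*% log(pmax(dens, 1e-300))) / pre$nSamp[[segName]]
      if (abs(.zscore(m)[me]) > rej@zLimit) { flagged <- TRUE; break }
    }
    if (flagged) {
      reasons <- c(reasons, paste0("statistical:", segName))
      next
    }
    rejIdx <- .iterativeReject(pre$bp[[segName]][grp, , drop = FALSE],
                               rej@zLimit, rej@maxIterations)
    if (me %in% rejIdx)
      reasons <- c(reasons, paste0("bandpower:", segName))
  }
  reasons
}

# map a classifier's selected features to columns of the engine feature array
.featureColumns <- function(clf, index) {
  vapply(seq_len(nrow(clf@selectedFeatures)), function(r)
    which(index$derivation == clf@selectedFeatures$derivation[r] &
            index$band == clf@selectedFeatures$band[r])[1],
    0L)
}

#' Simulate one adaptive BCI session (prequential)
#'
#' Processes an epoched session trial by trial, as an online system would:
#' each arriving in-scope trial is screened by the outlier pipeline (with
#' rejection statistics computed over the trials collected so far); once
#' every in-scope class has `nInitTpc` artifact-free trials the initial
#' calibration runs (in auto mode this includes automatic class-pair
#' selection, after which only the selected pair's trials are counted,
#' classified and evaluated); every later artifact-free trial is classified
#' at every valid timepoint with the most recent model; and the system
#' recalibrates on all collected artifact-free trials whenever every
#' in-scope class has accumulated `nUpdateTpc` new ones. The model applied
#' to a trial was always trained only on earlier trials.
#'
#' @param session an [EpochedSession-class]; its label set must cover the
#'   configured classes. Trials of other classes are skipped.
#' @param cfg an `AdaptiveConfig` from [adaptiveConfig()].
#' @return an [AdaptiveSessionResult-class]; if the stream ends before the
#'   initial calibration the result is flagged "never calibrated"
#' @export
runSession <- function(session, cfg) {
  stopifnot(inherits(cfg, "AdaptiveConfig"))
  if (!all(cfg$classes %in% session@labels))
    warning("some configured classes have no trials in the session")
  labels <- session@labels
  n <- nTrials(session)
  fs <- session@timing@fs
  nS <- dim(session@epochs)[3L]
  needed <- which(labels %in% cfg$classes)
  pre <- .engineFeatures(session, cfg, needed)

  scope <- sort(cfg$classes)
  acceptedByClass <- setNames(vector("list", length(scope)), scope)
  newCount <- setNames(rep(0L, length(scope)), scope)
  models <- list()
  modelArrivals <- integer(0)
  currentCols <- NULL
  selPairSorted <- character(0)
  predRows <- list()
  log <- data.frame(arrival = seq_len(n), label = labels,
                    inScope = FALSE, artifact = FALSE,
                    modelVersion = NA_integer_, evaluated = FALSE)
  rejNotes <- character(0)

  for (i in seq_len(n)) {
    lab <- labels[i]
    if (!lab %in% scope) next
    log$inScope[i] <- TRUE
    relaxPool <- sort(unlist(acceptedByClass, use.names = FALSE))
    reasons <- .screenTrial(pre, i, relaxPool, acceptedByClass[[lab]],
                            cfg$rejection)
    if (length(reasons)) {
      log$artifact[i] <- TRUE
      rejNotes <- c(rejNotes, sprintf("trial %d: %s", i,
                                      paste(reasons, collapse = ", ")))
      next
    }

    if (length(models)) {
      m <- models[[length(models)]]
      featT <- matrix(pre$vals[i, currentCols, ], nrow = length(currentCols))
      scores <- .ldaScores(list(weights = m@weights, bias = m@bias), featT)
      predRow <- rep(NA_integer_, nS)
      ok <- !is.na(scores)
      predRow[ok] <- ifelse(scores[ok] > 0, 1L, 2L)
      predRows[[as.character(i)]] <- predRow
      log$modelVersion[i] <- length(models)
      log$evaluated[i] <- TRUE
    }

    acceptedByClass[[lab]] <- c(acceptedByClass[[lab]], i)
    newCount[lab] <- newCount[lab] + 1L

    if (!length(models)) {
      counts <- vapply(acceptedByClass, length, 0L)
      if (all(counts >= cfg$nInitTpc)) {
        trainIdx <- sort(unlist(acceptedByClass, use.names = FALSE))
        if (cfg$mode == "auto") {
          res <- .autoSelectCore(pre$vals[trainIdx, , , drop = FALSE], pre$index,
                                 labels[trainIdx], fs, pre$validFrom,
                                 cfg$windowRange, cfg$featureSelection)
          selPairSorted <- sort(res$pair)
          scope <- selPairSorted
          acceptedByClass <- acceptedByClass[scope]
          newCount <- newCount[scope]
          models <- list(res$classifier)
        } else {
          res <- .calibrateCore(pre$vals[trainIdx, , , drop = FALSE], pre$index,
                                labels[trainIdx], fs, pre$validFrom,
                                cfg$windowRange,
                                featureSelection = cfg$featureSelection)
          selPairSorted <- sort(scope)
          models <- list(res$classifier)
        }
        modelArrivals <- i
        currentCols <- .featureColumns(models[[1]], pre$index)
        newCount[] <- 0L
      }
    } else {
      due <- if (cfg$updateRule == "per_class") all(newCount >= cfg$nUpdateTpc)
             else sum(newCount) >= cfg$nUpdateTpc
      if (due) {
        trainIdx <- sort(unlist(acceptedByClass, use.names = FALSE))
        res <- .calibrateCore(pre$vals[trainIdx, , , drop = FALSE], pre$index,
                              labels[trainIdx], fs, pre$validFrom,
                              cfg$windowRange,
                              featureSelection = cfg$featureSelection)
        models <- c(models, res$classifier)
        modelArrivals <- c(modelArrivals, i)
        currentCols <- .featureColumns(res$classifier, pre$index)
        newCount[] <- 0L
      }
    }
  }

  predictions <- if (length(predRows))
    do.call(rbind, predRows)
  else
    matrix(NA_integer_, 0L, nS)
  new("AdaptiveSessionResult",
      trialLog = log, predictions = predictions, models = models,
      modelArrivals = as.integer(modelArrivals),
      selectedPair = if (length(selPairSorted)) selPairSorted else c(NA_character_, NA_character_),
      calibrated = length(models) > 0L,
      timing = session@timing, validFrom = pre$validFrom)
}
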
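#' Construct trial timing
#'
#' Defaults follow the cue paradigm used throughout the package: relax from
#' second 0 to 3, cue at second 3, imagery analysed to second 8, trial end at
#' second 10, sampled at 256 Hz.
#'
#' @param relaxStart,relaxEnd,cueOnset,imageryEndAnalysis,trialEnd seconds.
#' @param fs sampling rate in Hz.
#' @return a [TrialTiming-class]
#' @export
trialTiming <- function(relaxStart = 0, relaxEnd = 3, cueOnset = 3,
                        imageryEndAnalysis = 8, trialEnd = 10, fs = 256) {
  new("TrialTiming", relaxStart = relaxStart, relaxEnd = relaxEnd,
      cueOnset = cueOnset, imageryEndAnalysis = imageryEndAnalysis,
      trialEnd = trialEnd, fs = fs)
}

.emptyLog <- function(n) list(trials = rep(list(NULL), n), notes = character(0))

#' Construct an epoched session
#'
#' @param epochs trials x channels x samples numeric array in microvolts.
#' @param labels per-trial class labels.
#' @param timing a [TrialTiming-class].
#' @param channelLabels electrode names; defaults to the array's dimnames or
#'   `Ch1..ChN`.
#' @return an [EpochedSession-class] with all-false artifact flags
#' @export
epochedSession <- function(epochs, labels, timing = trialTiming(),
                           channelLabels = NULL) {
  if (is.null(channelLabels))
    channelLabels <- dimnames(epochs)[[2]] %||% paste0("Ch", seq_len(dim(epochs)[2]))
  dimnames(epochs) <- list(NULL, channelLabels, NULL)
  new("EpochedSession", epochs = epochs, labels = as.character(labels),
      timing = timing, channelLabels = channelLabels,
      artifactFlags = rep(FALSE, dim(epochs)[1]),
      rejectionLog = .emptyLog(dim(epochs)[1]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct an outlier-rejection configuration
#'
#' @param amplitudeLimit microvolts (default 100); strict: a sample must
#'   exceed the limit in magnitude to reject.
#' @param zLimit SD multiples (default 3.5).
#' @param bands band edges for the iterative band-power phase.
#' @param maxIterations iteration cap for that phase (default 20).
#' @param excludeChannels electrode labels never screened (e.g. artifact-laden
#'   lateral channels excluded manually).
#' @param nBins histogram bins for the probability measure (default 100).
#' @return a [RejectionConfig-class]
#' @export
rejectionConfig <- function(amplitudeLimit = 100, zLimit = 3.5,
                            bands = defaultBands(), maxIterations = 20L,
                            excludeChannels = character(0), nBins = 100L) {
  new("RejectionConfig", amplitudeLimit = amplitudeLimit, zLimit = zLimit,
      bands = bands, maxIterations = as.integer(maxIterations),
      excludeChannels = excludeChannels, nBins = as.integer(nBins))
}

#' Cut epochs out of a continuous recording
#'
#' Each event marks a cue onset; the epoch starts `cueOnset` seconds before
#' it so that epoch time 0 is the relax-period start. Windows are half-open
#' `[start, end)`. Events whose epoch would run past either end of the
#' recording are dropped with a warning.
#'
#' @param continuous channels x samples numeric matrix (microvolts) with
#'   electrode row names.
#' @param events data.frame with columns `onset` (seconds) and `label`.
#' @param timing a [TrialTiming-class].
#' @return an [EpochedSession-class]
#' @export
extractEpochs <- function(continuous, events, timing = trialTiming()) {
  fs <- timing@fs
  nS <- round(timing@trialEnd * fs)
  nCh <- nrow(continuous)
  keep <- logical(nrow(events))
  starts <- integer(nrow(events))
  for (i in seq_len(nrow(events))) {
    start <- floor((events$onset[i] - timing@cueOnset) * fs) + 1L
    if (start >= 1L && start + nS - 1L <= ncol(continuous)) {
      keep[i] <- TRUE
      starts[i] <- start
    }
  }
  if (any(!keep))
    warning(sprintf("%d event(s) dropped: epoch extends beyond the recording",
                    sum(!keep)))
  idx <- which(keep)
  epochs <- array(0, c(length(idx), nCh, nS))
  for (k in seq_along(idx))
    epochs[k, , ] <- continuous[, starts[idx[k]] + 0:(nS - 1L)]
  epochedSession(epochs, events$label[idx], timing,
                 channelLabels = rownames(continuous) %||% paste0("Ch", seq_len(nCh)))
}

#' Amplitude criterion of the outlier rejection
#'
#' @param segment numeric vector, matrix or array of microvolt samples
#'   (all screened channels of one trial segment).
#' @param limit microvolts.
#' @return `TRUE` iff any sample strictly exceeds the limit in magnitude
#' @export
rejectAmplitude <- function(segment, limit = 100) {
  any(abs(segment) > limit)
}

.zscore <- function(v) {
  s <- sd(v)
  if (!is.finite(s) || s <= .Machine$double.eps * max(1, abs(mean(v))))
    return(rep(0, length(v)))   # zero spread: this measure rejects nothing
  (v - mean(v)) / s
}

.kurtosisByTrial <- function(x) {
  # x: trials x samples
  apply(x, 1L, e1071::kurtosis, type = 1L)
}

# smooth a histogram count vector with a small Gaussian kernel (density
# estimation; keeps sparse tail bins from dominating the log density)
.smoothCounts <- function(counts, sdBins = 1.5) {
  hw <- ceiling(3 * sdBins)
  k <- dnorm(seq(-hw, hw), sd = sdBins)
  k <- k / sum(k)
  padded <- c(numeric(hw), counts, numeric(hw))
  out <- vapply(seq_along(counts), function(i)
    sum(padded[i:(i + 2L * hw)] * k), 0)
  out * sum(counts) / sum(out)
}

# per-trial mean log empirical density; density fitted over pooled samples
.probMeasureByTrial <- function(x, nBins, edges = NULL) {
  # x: trials x samples
  if (is.null(edges)) {
    rng <- range(x)
    if (diff(rng) <= 0) return(rep(0, nrow(x)))
    edges <- seq(rng[1], rng[2], length.out = nBins + 1L)
  }
  bin <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- .smoothCounts(tabulate(bin, nbins = nBins))
  width <- diff(edges)
  dens <- counts / (length(x) * width)
  rowMeans(matrix(log(pmax(dens[bin], 1e-300)), nrow = nrow(x)))
}

#' Statistical (kurtosis/probability) outlier criterion
#'
#' Per channel, computes each trial's sample kurtosis and mean log empirical
#' probability (histogram density fitted over all trials' samples of that
#' channel) and z-scores both across trials. A trial is rejected when either
#' measure deviates by more than `zLimit` SD on any channel. With fewer than
#' three trials nothing is rejected; a measure with zero across-trial SD
#' rejects nothing.
#'
#' @param segments trials x channels x samples array (one segment per trial).
#' @param zLimit SD multiples.
#' @param nBins histogram bins for the probability measure.
#' @return sorted integer vector of rejected trial indices
#' @export
rejectStatistical <- function(segments, zLimit = 3.5, nBins = 100L) {
  nT <- dim(segments)[1L]
  if (nT < 3L) return(integer(0))
  bad <- logical(nT)
  for (ch in seq_len(dim(segments)[2L])) {
    x <- segments[, ch, , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, nrow = nT)
    bad <- bad | abs(.zscore(.kurtosisByTrial(x))) > zLimit
    bad <- bad | abs(.zscore(.probMeasureByTrial(x, nBins))) > zLimit
  }
  which(bad)
}

# iterative z-score rejection on a trials x measures value matrix;
# returns indices rejected across all passes
.iterativeReject <- function(vals, zLimit, maxIterations) {
  surviving <- seq_len(nrow(vals))
  for (it in seq_len(maxIterations)) {
    if (length(surviving) < 3L) break
    sub <- vals[surviving, , drop = FALSE]
    mu <- colMeans(sub)
    sdv <- apply(sub, 2L, sd)
    sdv[!is.finite(sdv) | sdv <= .Machine$double.eps] <- Inf  # inert column
    z <- abs(sweep(sweep(sub, 2L, mu), 2L, sdv, "/"))
    bad <- rowSums(z > zLimit) > 0L
    if (!any(bad)) break
    surviving <- surviving[!bad]
  }
  setdiff(seq_len(nrow(vals)), surviving)
}

# mean log band power of each (signal, band) within a sample-index window.
# signals: trials x signals x samples; causal filtering from segment start.
.segmentLogBandpower <- function(signals, bands, fs, idx) {
  nT <- dim(signals)[1L]; nSig <- dim(signals)[2L]; nB <- nrow(bands)
  vals <- matrix(0, nT, nSig * nB)
  for (s in seq_len(nSig)) {
    for (b in seq_len(nB)) {
      bf <- .butterBand(bands[b, 1], bands[b, 2], fs)
      col <- (s - 1L) * nB + b
      for (tr in seq_len(nT)) {
        filt <- as.numeric(signal::filter(bf, signals[tr, s, ]))
        vals[tr, col] <- log(pmax(mean(filt[idx]^2), 1e-10))
      }
    }
  }
  vals
}

#' Iterative band-power outlier criterion
#'
#' Repeatedly computes each trial's mean log band power for every
#' (signal, band) combination and rejects trials whose value lies beyond
#' `zLimit` SD of the surviving set, until a pass rejects nothing or the
#' iteration cap is reached.
#'
#' @param segments trials x signals x samples array (bipolar-derivation or
#'   channel signals of one segment).
#' @param bands numeric matrix (n x 2) of band edges in Hz.
#' @param fs sampling rate in Hz.
#' @param zLimit SD multiples.
#' @param maxIterations iteration cap.
#' @return sorted integer vector of rejected trial indices
#' @export
rejectBandpowerIterative <- function(segments, bands = defaultBands(), fs = 256,
                                     zLimit = 3.5, maxIterations = 20L) {
  if (dim(segments)[1L] < 3L) return(integer(0))
  vals <- .segmentLogBandpower(segments, bands, fs, seq_len(dim(segments)[3L]))
  .iterativeReject(vals, zLimit, maxIterations)
}

.logReject <- function(log, trials, phase, segment) {
  for (tr in trials)
    log$trials[[tr]] <- rbind(log$trials[[tr]],
                              data.frame(phase = phase, segment = segment))
  log
}

#' Three-phase trial-based outlier rejection
#'
#' Runs the full rejection pipeline on an epoched session and fills in the
#' artifact flags and the rejection log; signal values are never modified.
#' Phase order is amplitude, then kurtosis/probability, then iterative
#' band power. Each phase screens the relax segment with all classes pooled
#' and the imagery segment separately per class. A class with fewer than
#' three surviving trials skips the statistical and iterative phases for its
#' imagery segment (noted in the log).
#'
#' @param session an [EpochedSession-class].
#' @param cfg a [RejectionConfig-class].
#' @param derivations optional list of [BipolarDerivation-class]; when given,
#'   the iterative band-power phase screens the derivation signals and the
#'   amplitude/statistical phases screen the electrodes those derivations
#'   use. Otherwise all (non-excluded) channels are screened directly.
#' @return the session with `artifactFlags` and `rejectionLog` filled
#' @export
runOutlierPipeline <- function(session, cfg = rejectionConfig(), derivations = NULL) {
  tm <- session@timing
  fs <- tm@fs
  relaxIdx <- .windowIdx(tm@relaxStart, tm@relaxEnd, fs)
  imagIdx <- .windowIdx(tm@cueOnset, tm@imageryEndAnalysis, fs)
  nT <- nTrials(session)
  log <- .emptyLog(nT)
  flags <- rep(FALSE, nT)

  if (is.null(derivations)) {
    chans <- setdiff(session@channelLabels, cfg@excludeChannels)
    chIdx <- match(chans, session@channelLabels)
    raw <- session@epochs[, chIdx, , drop = FALSE]
    bpSig <- raw
  } else {
    elec <- unique(unlist(lapply(derivations, function(d) c(d@anode, d@cathode))))
    elec <- setdiff(elec, cfg@excludeChannels)
    chIdx <- match(elec, session@channelLabels)
    raw <- session@epochs[, chIdx, , drop = FALSE]
    bpSig <- derivationSignals(session, derivations)
  }

  # phase 1: amplitude, per trial, both segments
  for (tr in seq_len(nT)) {
    if (rejectAmplitude(raw[tr, , relaxIdx], cfg@amplitudeLimit)) {
      flags[tr] <- TRUE
      log <- .logReject(log, tr, "amplitude", "relax")
    }
    if (rejectAmplitude(raw[tr, , imagIdx], cfg@amplitudeLimit)) {
      flags[tr] <- TRUE
      log <- .logReject(log, tr, "amplitude", "imagery")
    }
  }

  groupsOf <- function(surv) {
    g <- list(list(name = "relax", idx = relaxIdx, trials = surv))
    for (cl in sort(unique(session@labels))) {
      g[[length(g) + 1L]] <- list(name = paste0("imagery:", cl), idx = imagIdx,
                                  trials = surv[session@labels[surv] == cl])
    }
    g
  }

  # phase 2: kurtosis / probability
  surv <- which(!flags)
  for (g in groupsOf(surv)) {
    if (length(g$trials) < 3L) {
      if (length(g$trials) > 0L)
        log$notes <- c(log$notes, sprintf(
          "statistical phase skipped for %s: fewer than 3 surviving trials", g$name))
      next
    }
    rej <- rejectStatistical(raw[g$trials, , g$idx, drop = FALSE],
                             cfg@zLimit, cfg@nBins)
    if (length(rej)) {
      flags[g$trials[rej]] <- TRUE
      log <- .logReject(log, g$trials[rej], "statistical", g$name)
    }
  }

  # phase 3: iterative band power
  surv <- which(!flags)
  for (g in groupsOf(surv)) {
    if (length(g$trials) < 3L) {
      if (length(g$trials) > 0L)
        log$notes <- c(log$notes, sprintf(
          "band-power phase skipped for %s: fewer than 3 surviving trials", g$name))
      next
    }
    rej <- rejectBandpowerIterative(bpSig[g$trials, , g$idx, drop = FALSE],
                                    cfg@bands, fs, cfg@zLimit, cfg@maxIterations)
    if (length(rej)) {
      flags[g$trials[rej]] <- TRUE
      log <- .logReject(log, g$trials[rej], "bandpower", g$name)
    }
  }

  session@artifactFlags <- flags
  session@rejectionLog <- log
  session
}
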
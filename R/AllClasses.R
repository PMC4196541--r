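#' @import methods
#' @importFrom stats median sd var rnorm runif rbinom fft pbinom quantile setNames
#' @importFrom utils head combn
NULL

#' Electrode grid (montage)
#'
#' A sparse rectangular grid of scalp electrodes. Rows index coronal lines
#' (front to back), columns index sagittal lines (left to right); a 10/20
#' montage occupies only some positions of the grid.
#'
#' @slot labels character vector of unique electrode names.
#' @slot coords integer matrix (one row per electrode, columns `row`, `col`)
#'   giving the grid position of each electrode; positions are unique.
#' @seealso [electrodeGrid()], [defaultMontage()], [enumerateDerivations()]
#' @export
setClass("ElectrodeGrid",
  representation(labels = "character", coords = "matrix"),
  validity = function(object) {
    msg <- character(0)
    n <- length(object@labels)
    if (anyDuplicated(object@labels))
      msg <- c(msg, "electrode labels must be unique")
    if (!is.numeric(object@coords) || nrow(object@coords) != n || ncol(object@coords) != 2L)
      msg <- c(msg, "coords must be an n x 2 numeric matrix (row, col)")
    else {
      if (any(object@coords != round(object@coords)))
        msg <- c(msg, "grid coordinates must be integers")
      if (anyDuplicated(object@coords, MARGIN = 1))
        msg <- c(msg, "grid positions must be unique")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Bipolar derivation
#'
#' The difference signal between two electrodes lying on one grid line, in
#' sagittal (same column) or coronal (same row) orientation, with zero or
#' more skipped intermediate grid positions ("gaps"). The `covered` slot
#' holds every grid position from anode to cathode inclusive; it defines the
#' scalp area used by the overlap predicate of the greedy channel selection.
#'
#' @slot anode,cathode electrode labels; the output is anode minus cathode.
#' @slot orientation `"sagittal"` or `"coronal"`.
#' @slot gap integer, number of intermediate grid positions skipped.
#' @slot covered integer matrix of covered grid positions (row, col).
#' @seealso [bipolarDerivation()], [derivationsOverlap()], [applyDerivation()]
#' @export
setClass("BipolarDerivation",
  representation(anode = "character", cathode = "character",
                 orientation = "character", gap = "integer",
                 covered = "matrix"),
  validity = function(object) {
    msg <- character(0)
    if (object@anode == object@cathode)
      msg <- c(msg, "anode and cathode must differ")
    if (!object@orientation %in% c("sagittal", "coronal"))
      msg <- c(msg, "orientation must be 'sagittal' or 'coronal'")
    if (object@gap < 0L)
      msg <- c(msg, "gap must be >= 0")
    if (nrow(object@covered) != object@gap + 2L)
      msg <- c(msg, "covered must contain gap + 2 grid positions")
    if (length(msg)) msg else TRUE
  }
)

#' Trial timing of the cue paradigm
#'
#' Timing of one trial in a cue-guided (Graz-style) paradigm: a relax period,
#' a visual cue, and a sustained mental-imagery period. Times are in seconds
#' from trial start; `imageryEndAnalysis` bounds the part of the imagery
#' period used by outlier rejection and calibration windows.
#'
#' @slot relaxStart,relaxEnd,cueOnset,imageryEndAnalysis,trialEnd numeric seconds.
#' @slot fs sampling rate in Hz.
#' @seealso [trialTiming()]
#' @export
setClass("TrialTiming",
  representation(relaxStart = "numeric", relaxEnd = "numeric", cueOnset = "numeric",
                 imageryEndAnalysis = "numeric", trialEnd = "numeric", fs = "numeric"),
  validity = function(object) {
    ok <- object@relaxStart < object@relaxEnd &&
      object@relaxEnd <= object@cueOnset &&
      object@cueOnset < object@imageryEndAnalysis &&
      object@imageryEndAnalysis <= object@trialEnd
    if (!ok)
      return("timing must satisfy relaxStart < relaxEnd <= cueOnset < imageryEndAnalysis <= trialEnd")
    if (object@fs <= 0) return("fs must be positive")
    TRUE
  }
)

#' Epoched EEG session
#'
#' Per-trial EEG segments (microvolts) with class labels, trial timing,
#' channel labels, and artifact bookkeeping filled in by the outlier
#' rejection pipeline.
#'
#' @slot epochs numeric array, trials x channels x samples, in microvolts.
#' @slot labels character vector of per-trial class labels.
#' @slot timing a [TrialTiming-class] object.
#' @slot channelLabels character vector of electrode names (second dimension).
#' @slot artifactFlags logical per-trial flag, `TRUE` = artifact.
#' @slot rejectionLog list with elements `trials` (per-trial list of
#'   data.frames with columns `phase`, `segment`) and `notes` (character).
#' @seealso [epochedSession()], [extractEpochs()], [runOutlierPipeline()]
#' @export
setClass("EpochedSession",
  representation(epochs = "array", labels = "character", timing = "TrialTiming",
                 channelLabels = "character", artifactFlags = "logical",
                 rejectionLog = "list"),
  validity = function(object) {
    d <- dim(object@epochs)
    msg <- character(0)
    if (length(d) != 3L)
      return("epochs must be a trials x channels x samples array")
    if (length(object@labels) != d[1L])
      msg <- c(msg, "one label per trial required")
    if (length(object@channelLabels) != d[2L])
      msg <- c(msg, "one channel label per channel required")
    if (length(object@artifactFlags) != d[1L])
      msg <- c(msg, "one artifact flag per trial required")
    nS <- round(object@timing@trialEnd * object@timing@fs)
    if (d[3L] != nS)
      msg <- c(msg, sprintf("sample count (%d) must equal trialEnd * fs (%d)", d[3L], nS))
    if (length(msg)) msg else TRUE
  }
)

#' Outlier-rejection configuration
#'
#' Thresholds of the three-phase trial-based outlier rejection: an absolute
#' amplitude limit, a z-score limit for the kurtosis/probability measures and
#' the iterative band-power phase, the band set used by the latter, and an
#' iteration cap.
#'
#' @slot amplitudeLimit microvolts; samples beyond +/- this reject the trial.
#' @slot zLimit standard-deviation multiples for the statistical phases.
#' @slot bands numeric matrix (n x 2) of band edges in Hz.
#' @slot maxIterations cap for the iterative band-power phase.
#' @slot excludeChannels electrode labels excluded from screening.
#' @slot nBins histogram bins for the probability measure.
#' @seealso [rejectionConfig()], [runOutlierPipeline()]
#' @export
setClass("RejectionConfig",
  representation(amplitudeLimit = "numeric", zLimit = "numeric", bands = "matrix",
                 maxIterations = "integer", excludeChannels = "character",
                 nBins = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (object@amplitudeLimit <= 0) msg <- c(msg, "amplitudeLimit must be > 0")
    if (object@zLimit <= 0) msg <- c(msg, "zLimit must be > 0")
    if (ncol(object@bands) != 2L || any(object@bands[, 1] >= object@bands[, 2]))
      msg <- c(msg, "bands must be an n x 2 matrix with low < high")
    if (object@maxIterations < 1L) msg <- c(msg, "maxIterations must be >= 1")
    if (object@nBins < 2L) msg <- c(msg, "nBins must be >= 2")
    if (length(msg)) msg else TRUE
  }
)

#' Synthetic-session generator specification
#'
#' Full parameterization of a synthetic cue-paradigm EEG session:
#' class-conditional band-power effects (ERD/ERS), baseline rhythm
#' amplitudes, background noise, artifact injection, and the seed.
#'
#' @slot grid an [ElectrodeGrid-class].
#' @slot timing a [TrialTiming-class].
#' @slot classes class labels (cue conditions).
#' @slot runs,trialsPerClassPerRun paradigm counts; a run holds
#'   `length(classes) * trialsPerClassPerRun` trials in random order.
#' @slot effectMatrix numeric array classes x electrodes x bands of fractional
#'   band-power change during imagery (negative = ERD, positive = ERS); all
#'   values must be >= -1.
#' @slot rhythmAmplitudes numeric matrix electrodes x bands of baseline
#'   oscillation RMS amplitude in microvolts.
#' @slot noiseSd white-noise SD in microvolts.
#' @slot pinkNoiseScale 1/f background SD in microvolts.
#' @slot rhythmTrialSd SD (log scale) of the per-trial, per-band lognormal
#'   rhythm-amplitude drift shared across channels (vigilance-like
#'   trial-to-trial variability).
#' @slot backgroundTrialSd SD (log scale) of the per-trial lognormal gain of
#'   the background noise.
#' @slot artifactRate fraction of trials receiving artifact spikes.
#' @slot artifactAmplitude spike amplitude in microvolts.
#' @slot bands numeric matrix (n x 2) of rhythm band edges in Hz.
#' @slot seed integer RNG seed; same seed gives a byte-identical session.
#' @seealso [generatorSpec()], [generateSession()], [makeCohort()]
#' @export
setClass("GeneratorSpec",
  representation(grid = "ElectrodeGrid", timing = "TrialTiming", classes = "character",
                 runs = "integer", trialsPerClassPerRun = "integer",
                 effectMatrix = "array", rhythmAmplitudes = "matrix",
                 noiseSd = "numeric", pinkNoiseScale = "numeric",
                 rhythmTrialSd = "numeric", backgroundTrialSd = "numeric",
                 artifactRate = "numeric", artifactAmplitude = "numeric",
                 bands = "matrix", seed = "integer"),
  validity = function(object) {
    msg <- character(0)
    nC <- length(object@classes); nE <- length(object@grid@labels); nB <- nrow(object@bands)
    if (!identical(dim(object@effectMatrix), c(nC, nE, nB)))
      msg <- c(msg, "effectMatrix must be classes x electrodes x bands")
    else if (any(object@effectMatrix < -1))
      msg <- c(msg, "effect values must be >= -1 (power cannot drop below zero)")
    if (!identical(dim(object@rhythmAmplitudes), c(nE, nB)))
      msg <- c(msg, "rhythmAmplitudes must be electrodes x bands")
    if (object@artifactRate < 0 || object@artifactRate > 1)
      msg <- c(msg, "artifactRate must be in [0, 1]")
    if (object@runs < 1L || object@trialsPerClassPerRun < 1L)
      msg <- c(msg, "runs and trialsPerClassPerRun must be >= 1")
    if (length(msg)) msg else TRUE
  }
)

#' Calibrated pairwise classifier
#'
#' A linear discriminant over selected log band-power features of one class
#' pair, together with the 0.5 s training window chosen by leave-one-out
#' cross-validation and the scores that justified the choice.
#'
#' @slot classPair the two class labels the discriminant separates; a
#'   positive decision score predicts the first.
#' @slot selectedFeatures data.frame with columns `derivation` (label),
#'   `band` (index), one row per feature used.
#' @slot trainWindow numeric `[start, end)` in seconds (width 0.5).
#' @slot weights,bias linear discriminant parameters.
#' @slot loocvMedianAccuracy LooCV median accuracy of the chosen window.
#' @slot bestFeatureFisher Fisher score of the best selected feature (used as
#'   tie-break in automatic class-pair selection).
#' @seealso [calibrate()], [autoSelectClasses()]
#' @export
setClass("CalibratedClassifier",
  representation(classPair = "character", selectedFeatures = "data.frame",
                 trainWindow = "numeric", weights = "numeric", bias = "numeric",
                 loocvMedianAccuracy = "numeric", bestFeatureFisher = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@classPair) != 2L)
      msg <- c(msg, "classPair must hold exactly two labels")
    if (length(object@trainWindow) != 2L ||
        abs(diff(object@trainWindow) - 0.5) > 1e-9)
      msg <- c(msg, "trainWindow must be a 0.5 s interval")
    if (length(object@weights) != nrow(object@selectedFeatures))
      msg <- c(msg, "one weight per selected feature required")
    if (length(object@loocvMedianAccuracy) == 1L &&
        (object@loocvMedianAccuracy < 0 || object@loocvMedianAccuracy > 1))
      msg <- c(msg, "loocvMedianAccuracy must be in [0, 1]")
    if (length(msg)) msg else TRUE
  }
)

#' Result of one simulated online (prequential) session
#'
#' Per-trial bookkeeping of an adaptive BCI simulation: what arrived, what
#' was rejected, which model version classified each trial, the per-timepoint
#' predictions of every evaluated trial, and the model lineage.
#'
#' @slot trialLog data.frame, one row per arriving trial: `arrival`, `label`,
#'   `inScope`, `artifact`, `modelVersion` (NA before calibration),
#'   `evaluated`.
#' @slot predictions integer matrix (evaluated trials x samples); entries are
#'   1/2 indices into `classes` of the predicting model, NA where the feature
#'   time course is not yet valid. Row names give arrival indices.
#' @slot models list of [CalibratedClassifier-class], in training order.
#' @slot modelArrivals arrival index that triggered each (re)calibration.
#' @slot selectedPair the class pair in use after initial calibration.
#' @slot calibrated `FALSE` if the stream ended before initial calibration.
#' @slot timing the session's [TrialTiming-class].
#' @slot validFrom seconds of feature warm-up at the start of each trial.
#' @seealso [runSession()], [accuracyTimecourse()]
#' @export
setClass("AdaptiveSessionResult",
  representation(trialLog = "data.frame", predictions = "matrix", models = "list",
                 modelArrivals = "integer", selectedPair = "character",
                 calibrated = "logical", timing = "TrialTiming",
                 validFrom = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@models) != length(object@modelArrivals))
      msg <- c(msg, "one trigger arrival per model required")
    if (length(object@modelArrivals) > 1L && any(diff(object@modelArrivals) <= 0))
      msg <- c(msg, "model versions must be strictly increasing in arrival index")
    if (!object@calibrated && length(object@models) > 0L)
      msg <- c(msg, "an uncalibrated result cannot carry models")
    if (length(msg)) msg else TRUE
  }
)

setMethod("show", "ElectrodeGrid", function(object) {
  cat(sprintf("ElectrodeGrid with %d electrodes on a %d x %d grid\n",
              length(object@labels),
              diff(range(object@coords[, 1])) + 1L,
              diff(range(object@coords[, 2])) + 1L))
  cat("  ", paste(head(object@labels, 10L), collapse = " "),
      if (length(object@labels) > 10L) "..." else "", "\n")
})

setMethod("show", "BipolarDerivation", function(object) {
  cat(sprintf("BipolarDerivation %s-%s (%s, gap %d)\n",
              object@anode, object@cathode, object@orientation, object@gap))
})

setMethod("show", "TrialTiming", function(object) {
  cat(sprintf("TrialTiming: relax [%g, %g) s, cue %g s, imagery to %g s, trial %g s, fs %g Hz\n",
              object@relaxStart, object@relaxEnd, object@cueOnset,
              object@imageryEndAnalysis, object@trialEnd, object@fs))
})

setMethod("show", "EpochedSession", function(object) {
  d <- dim(object@epochs)
  cat(sprintf("EpochedSession: %d trials x %d channels x %d samples (%g Hz)\n",
              d[1], d[2], d[3], object@timing@fs))
  tab <- table(object@labels)
  cat("  classes:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  artifact-flagged trials: %d\n", sum(object@artifactFlags)))
})

setMethod("show", "CalibratedClassifier", function(object) {
  cat(sprintf("CalibratedClassifier: %s vs %s\n", object@classPair[1], object@classPair[2]))
  cat(sprintf("  window [%g, %g) s, LooCV median accuracy %.3f\n",
              object@trainWindow[1], object@trainWindow[2], object@loocvMedianAccuracy))
  cat(sprintf("  features: %s\n",
              paste(sprintf("%s/band%d", object@selectedFeatures$derivation,
                            object@selectedFeatures$band), collapse = ", ")))
})

setMethod("show", "AdaptiveSessionResult", function(object) {
  cat(sprintf("AdaptiveSessionResult: %d trials processed, %d models, %s\n",
              nrow(object@trialLog), length(object@models),
              if (object@calibrated)
                sprintf("pair %s vs %s", object@selectedPair[1], object@selectedPair[2])
              else "never calibrated"))
  cat(sprintf("  evaluated trials: %d, artifacts: %d\n",
              sum(object@trialLog$evaluated), sum(object@trialLog$artifact)))
})

setMethod("show", "GeneratorSpec", function(object) {
  cat(sprintf("GeneratorSpec: %d classes x %d runs x %d trials/class/run on %d electrodes (seed %d)\n",
              length(object@classes), object@runs, object@trialsPerClassPerRun,
              length(object@grid@labels), object@seed))
})

# ---- accessors ----

#' Number of trials in an epoched session
#' @param x an [EpochedSession-class]
#' @return integer trial count
#' @export
nTrials <- function(x) dim(x@epochs)[1L]

#' Trial class labels
#' @param x an [EpochedSession-class]
#' @return character vector of per-trial labels
#' @export
trialLabels <- function(x) x@labels

#' Per-trial artifact flags
#' @param x an [EpochedSession-class] or [AdaptiveSessionResult-class]
#' @return logical vector, `TRUE` = artifact
#' @export
artifactFlags <- function(x) {
  if (is(x, "AdaptiveSessionResult")) x@trialLog$artifact else x@artifactFlags
}

#' Channel labels of an epoched session
#' @param x an [EpochedSession-class]
#' @return character vector of electrode names
#' @export
channelLabels <- function(x) x@channelLabels

#' Epoch data array
#' @param x an [EpochedSession-class]
#' @return trials x channels x samples array in microvolts
#' @export
epochData <- function(x) x@epochs

#' Trial timing of a session or result
#' @param x an [EpochedSession-class] or [AdaptiveSessionResult-class]
#' @return a [TrialTiming-class]
#' @export
sessionTiming <- function(x) x@timing

#' Rejection log of an epoched session
#' @param x an [EpochedSession-class]
#' @return list with per-trial rejection records and notes
#' @export
rejectionLog <- function(x) x@rejectionLog

#' Model history of an adaptive run
#' @param x an [AdaptiveSessionResult-class]
#' @return list of [CalibratedClassifier-class] in training order
#' @export
modelHistory <- function(x) x@models

#' Class pair selected by an adaptive run
#' @param x an [AdaptiveSessionResult-class] or [CalibratedClassifier-class]
#' @return character vector of two class labels
#' @export
selectedPair <- function(x) {
  if (is(x, "CalibratedClassifier")) x@classPair else x@selectedPair
}
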
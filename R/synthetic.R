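#' Default baseline rhythm amplitudes
#'
#' Baseline RMS amplitude (microvolts) of the narrowband oscillation of each
#' electrode x band cell. Alpha-range rhythms are strongest, beta weaker,
#' everywhere on the grid; class effects then modulate these amplitudes
#' site- and band-specifically.
#'
#' @param grid an [ElectrodeGrid-class].
#' @param bands band-edge matrix.
#' @return numeric matrix electrodes x bands
#' @export
defaultRhythmAmplitudes <- function(grid = defaultMontage(), bands = defaultBands()) {
  perBand <- c(3.5, 3.5, 2.5, 2.5, 1.5)[seq_len(nrow(bands))]
  matrix(rep(perBand, each = length(grid@labels)),
         length(grid@labels), nrow(bands),
         dimnames = list(grid@labels, rownames(bands)))
}

# set template cells, silently skipping classes/electrodes/bands the spec
# does not have (reduced montages and class subsets are common in tests)
.setEffect <- function(eff, class, electrodes, bands, value) {
  dn <- dimnames(eff)
  if (!class %in% dn[[1]]) return(eff)
  for (e in intersect(electrodes, dn[[2]]))
    for (b in bands[bands <= dim(eff)[3]])
      eff[class, e, b] <- value
  eff
}

#' Default class-conditional effect template ("strong effect")
#'
#' Fractional band-power changes during imagery (negative = ERD) for the five
#' mental tasks, focal at the sites the packaged default derivations cover:
#' hand imagery desynchronizes mu/low-beta over the left sensorimotor and
#' vertex region, foot imagery desynchronizes alpha at the vertex, word
#' generation strongly modulates parietal beta, mental arithmetic modulates
#' right-parietal alpha, and spatial navigation is nearly silent. The
#' magnitudes are calibrated so the best single-trial feature Fisher score
#' of the designed-best pair (Hand, Word) is about 1 under default noise.
#'
#' @param grid an [ElectrodeGrid-class].
#' @param classes class labels (default the five cue conditions).
#' @param bands band-edge matrix.
#' @return numeric array classes x electrodes x bands
#' @export
defaultEffectMatrix <- function(grid = defaultMontage(),
                                classes = c("Feet", "Hand", "Word", "Math", "Nav"),
                                bands = defaultBands()) {
  eff <- array(0, c(length(classes), length(grid@labels), nrow(bands)),
               dimnames = list(classes, grid@labels, rownames(bands)))
  # Hand and Word modulate the same sites in opposite directions (ERD vs
  # ERS), so their mutual contrast is roughly twice either class's contrast
  # against the remaining tasks.
  eff <- .setEffect(eff, "Hand", c("FCz", "CPz"), 2, -0.45)
  eff <- .setEffect(eff, "Hand", c("C3", "CP3"), 2, -0.35)
  eff <- .setEffect(eff, "Hand", c("P1", "P2", "Pz", "CP4", "PO4"), 4, 0.45)
  eff <- .setEffect(eff, "Word", c("FCz", "CPz"), 2, 0.45)
  eff <- .setEffect(eff, "Word", c("P1", "P2", "Pz", "CP4", "PO4"), 4, -0.45)
  eff <- .setEffect(eff, "Feet", c("FCz", "CPz"), 1, -0.20)
  eff <- .setEffect(eff, "Math", c("CP4", "PO4"), 2, -0.20)
  eff <- .setEffect(eff, "Nav", "POz", 1, -0.10)
  eff
}

#' Construct a generator specification
#'
#' Defaults reproduce the cue paradigm the package targets: five mental-task
#' classes, eight runs of five trials per class (200 trials), 30 electrodes,
#' 256 Hz, with the strong-effect template of [defaultEffectMatrix()] and no
#' injected artifacts.
#'
#' @param grid an [ElectrodeGrid-class].
#' @param timing a [TrialTiming-class].
#' @param classes class labels.
#' @param runs,trialsPerClassPerRun paradigm counts.
#' @param effectMatrix classes x electrodes x bands fractional power change.
#' @param rhythmAmplitudes electrodes x bands baseline RMS amplitude (uV).
#' @param noiseSd white-noise SD in uV.
#' @param pinkNoiseScale 1/f noise SD in uV.
#' @param rhythmTrialSd log-scale SD of the per-trial, per-band rhythm
#'   amplitude drift (trial-to-trial band-power variability; 0 disables).
#' @param backgroundTrialSd log-scale SD of the per-trial background gain.
#' @param artifactRate fraction of trials receiving artifact spikes.
#' @param artifactAmplitude spike amplitude in uV (default 150).
#' @param bands band-edge matrix for the rhythms.
#' @param seed integer RNG seed.
#' @return a [GeneratorSpec-class]
#' @export
generatorSpec <- function(grid = defaultMontage(), timing = trialTiming(),
                          classes = c("Feet", "Hand", "Word", "Math", "Nav"),
                          runs = 8L, trialsPerClassPerRun = 5L,
                          effectMatrix = defaultEffectMatrix(grid, classes, bands),
                          rhythmAmplitudes = defaultRhythmAmplitudes(grid, bands),
                          noiseSd = 5, pinkNoiseScale = 5,
                          rhythmTrialSd = 0, backgroundTrialSd = 0,
                          artifactRate = 0, artifactAmplitude = 150,
                          bands = defaultBands(), seed = 1L) {
  new("GeneratorSpec", grid = grid, timing = timing, classes = as.character(classes),
      runs = as.integer(runs), trialsPerClassPerRun = as.integer(trialsPerClassPerRun),
      effectMatrix = effectMatrix, rhythmAmplitudes = rhythmAmplitudes,
      noiseSd = noiseSd, pinkNoiseScale = pinkNoiseScale,
      rhythmTrialSd = rhythmTrialSd, backgroundTrialSd = backgroundTrialSd,
      artifactRate = artifactRate, artifactAmplitude = artifactAmplitude,
      bands = bands, seed = as.integer(seed))
}

#' Designed-best class pair of a generator specification
#'
#' The pair with the largest summed squared log band-power contrast over all
#' electrode x band cells, i.e. the pair a perfect decoder should find
#' easiest to separate.
#'
#' @param spec a [GeneratorSpec-class].
#' @return character vector of two class labels (sorted)
#' @export
designedBestPair <- function(spec) {
  classes <- spec@classes
  pairs <- combn(sort(classes), 2L)
  contrast <- vapply(seq_len(ncol(pairs)), function(p) {
    e1 <- spec@effectMatrix[pairs[1, p], , ]
    e2 <- spec@effectMatrix[pairs[2, p], , ]
    sum((log1p(e1) - log1p(e2))^2)
  }, 0)
  pairs[, which.max(contrast)]
}

# Frequency-domain Gaussian-noise synthesis. Filling a spectrum with
# independent complex-Gaussian coefficients (no Hermitian symmetry) and
# inverse-transforming yields a complex signal whose real and imaginary
# parts are two independent Gaussian processes with that spectral shape,
# so one FFT serves two channels.
.shapedNoisePair <- function(L, shape) {
  idx <- which(shape > 0)
  Z <- complex(L)
  Z[idx] <- complex(real = rnorm(length(idx)), imaginary = rnorm(length(idx))) *
    shape[idx]
  y <- fft(Z, inverse = TRUE)
  re <- Re(y); im <- Im(y)
  list(re / sd(re), im / sd(im))
}

# unit-SD aperiodic ("pink") background, two independent channels.
# Band-limited to the acquisition pass band (0.5-100 Hz) like the
# amplifier's analog filter, with a spectral knee at 2 Hz: EEG aperiodic
# spectra follow 1/f only above a low-frequency knee, and an unbroken 1/f
# would put most power into a handful of ultra-slow components, making
# short-window power estimates unrealistically heavy-tailed.
.pinkNoisePair <- function(L, fs, low = 0.5, high = 100, knee = 2) {
  k <- 0:(L - 1)
  f <- pmin(k, L - k) * fs / L
  shape <- ifelse(f >= low & f <= pmin(high, fs / 2), 1 / sqrt(pmax(f, knee)), 0)
  .shapedNoisePair(L, shape)
}

# unit-SD band-limited Gaussian carriers, two independent channels
.bandNoisePair <- function(L, fs, low, high) {
  k <- 0:(L - 1)
  f <- pmin(k, L - k) * fs / L
  .shapedNoisePair(L, as.numeric(f >= low & f < high & k != 0))
}

# raised-cosine ramp (0 -> 1) of the imagery gain, per trial sample grid
.gainRamp <- function(timing, rampDur = 0.25) {
  fs <- timing@fs
  nS <- round(timing@trialEnd * fs)
  t <- (seq_len(nS) - 1L) / fs
  r <- numeric(nS)
  inRamp <- t >= timing@cueOnset & t < timing@cueOnset + rampDur
  r[inRamp] <- 0.5 * (1 - cos(pi * (t[inRamp] - timing@cueOnset) / rampDur))
  r[t >= timing@cueOnset + rampDur] <- 1
  r
}

#' Generate a synthetic cue-paradigm EEG session
#'
#' Every trial's channel signal is the sum of aperiodic 1/f background noise
#' (band-limited to the 0.5-100 Hz acquisition pass band, with a 2 Hz
#' spectral knee), white sensor noise, and one amplitude-modulated narrowband
#' oscillation per band (band-limited Gaussian noise carriers, so band-power
#' estimates have realistic variance). During the imagery period each band's
#' amplitude is
#' scaled by `sqrt(1 + effect(class, electrode, band))` — band power changes
#' by the effect fraction — with a 250 ms raised-cosine ramp at cue onset.
#' Cue order is randomized within each run over the per-class multiset.
#' Artifact trials receive high-amplitude spikes on all channels, guaranteed
#' to violate the amplitude rejection rule. Fully reproducible from the
#' seed.
#'
#' @param spec a [GeneratorSpec-class].
#' @param continuous if `TRUE`, also return the continuous recording
#'   (channels x samples, trials back to back) and the cue event table.
#' @return list with `session` (an [EpochedSession-class]; artifact flags
#'   all false — rejection is the decoder's job) and `truth` (labels, the
#'   true artifact flags, the effect matrix, and the designed best pair);
#'   with `continuous = TRUE` also `continuous` and `events`
#' @export
generateSession <- function(spec, continuous = FALSE) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec@seed)

  tm <- spec@timing
  fs <- tm@fs
  nS <- round(tm@trialEnd * fs)
  classes <- spec@classes
  runClasses <- rep(classes, spec@trialsPerClassPerRun)
  labels <- unlist(lapply(seq_len(spec@runs), function(r)
    runClasses[sample.int(length(runClasses))]))
  n <- length(labels)
  L <- n * nS
  # exact fraction of artifact trials, at random positions
  nArt <- round(spec@artifactRate * n)
  artifact <- rep(FALSE, n)
  if (nArt > 0) artifact[sample.int(n, nArt)] <- TRUE
  # trial-to-trial amplitude variability (vigilance-like), shared across channels
  bgGain <- if (spec@backgroundTrialSd > 0)
    exp(rnorm(n, sd = spec@backgroundTrialSd)) else rep(1, n)
  rhythmGain <- if (spec@rhythmTrialSd > 0)
    matrix(exp(rnorm(n * nrow(spec@bands), sd = spec@rhythmTrialSd)),
           n, nrow(spec@bands))
  else matrix(1, n, nrow(spec@bands))
  bgGainLong <- rep(bgGain, each = nS)

  ramp <- .gainRamp(tm)
  grid <- spec@grid
  nCh <- length(grid@labels)
  epochs <- array(0, c(n, nCh, nS))
  classIdx <- match(labels, classes)

  chPairs <- split(seq_len(nCh), ceiling(seq_len(nCh) / 2))
  for (pair in chPairs) {
    pink <- .pinkNoisePair(L, fs)
    x <- lapply(seq_along(pair), function(j)
      bgGainLong * (pink[[j]] * spec@pinkNoiseScale + rnorm(L, sd = spec@noiseSd)))
    for (b in seq_len(nrow(spec@bands))) {
      carriers <- .bandNoisePair(L, fs, spec@bands[b, 1], spec@bands[b, 2])
      for (j in seq_along(pair)) {
        ch <- pair[j]
        A <- spec@rhythmAmplitudes[ch, b]
        if (A <= 0) next
        g <- sqrt(1 + spec@effectMatrix[, ch, b])[classIdx]  # per-trial gain
        env <- rhythmGain[, b] * (1 + outer(g - 1, ramp))    # trials x samples
        x[[j]] <- x[[j]] + A * as.vector(t(env)) * carriers[[j]]
      }
    }
    for (j in seq_along(pair))
      epochs[, pair[j], ] <- matrix(x[[j]], n, nS, byrow = TRUE)
  }

  if (any(artifact)) {
    t <- (seq_len(nS) - 1L) / fs
    for (tr in which(artifact)) {
      centers <- c(runif(1, tm@relaxStart + 0.1, tm@relaxEnd - 0.1),
                   runif(1, tm@cueOnset + 0.1, tm@imageryEndAnalysis - 0.1),
                   runif(3, tm@relaxStart, tm@trialEnd))
      amps <- spec@artifactAmplitude * runif(5, 1.0, 1.4) *
        sample(c(-1, 1), 5, replace = TRUE)
      gains <- runif(nCh, 0.8, 1.2)
      pulse <- numeric(nS)
      for (s in seq_along(centers))
        pulse <- pulse + amps[s] * exp(-(t - centers[s])^2 / (2 * 0.01^2))
      epochs[tr, , ] <- epochs[tr, , ] + outer(gains, pulse)
    }
  }

  dimnames(epochs) <- list(NULL, grid@labels, NULL)
  session <- epochedSession(epochs, labels, tm, grid@labels)
  truth <- list(labels = labels, artifactFlags = artifact,
                effectMatrix = spec@effectMatrix,
                bestPair = designedBestPair(spec), seed = spec@seed)
  out <- list(session = session, truth = truth)
  if (continuous) {
    cont <- matrix(0, nCh, L, dimnames = list(grid@labels, NULL))
    for (ch in seq_len(nCh)) cont[ch, ] <- as.vector(t(epochs[, ch, ]))
    out$continuous <- cont
    out$events <- data.frame(onset = (seq_len(n) - 1L) * tm@trialEnd + tm@cueOnset,
                             label = labels)
  }
  out
}

#' Jittered multi-subject cohort of generator specifications
#'
#' Each subject's effect magnitudes are scaled by a lognormal multiplier
#' with unit mean and the given coefficient of variation, and each subject
#' gets a distinct derived seed. Deterministic from `seed`.
#'
#' @param baseSpec a [GeneratorSpec-class].
#' @param nSubjects number of subjects (>= 1).
#' @param interSubjectSd SD of the lognormal effect multiplier (0 = identical
#'   effects).
#' @param seed integer seed for the jitter and the derived per-subject seeds.
#' @return list of [GeneratorSpec-class], one per subject
#' @export
makeCohort <- function(baseSpec, nSubjects, interSubjectSd = 0.2, seed = 1L) {
  stopifnot(nSubjects >= 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  mult <- if (interSubjectSd > 0)
    exp(rnorm(nSubjects, mean = -interSubjectSd^2 / 2, sd = interSubjectSd))
  else rep(1, nSubjects)
  lapply(seq_len(nSubjects), function(s) {
    sp <- baseSpec
    sp@effectMatrix <- pmax(baseSpec@effectMatrix * mult[s], -0.95)
    sp@seed <- as.integer(seed + 7919L * s)
    validObject(sp)
    sp
  })
}
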
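# Fixtures are built in code; nothing is read from disk.

# two-electrode grid and its single bipolar derivation
pairGrid <- function() electrodeGrid(c("A", "B"), rows = c(1, 1), cols = c(1, 2))
pairDerivation <- function(grid = pairGrid()) bipolarDerivation(grid, "A", "B")

# compact trial timing for unit tests (same paradigm, lower rate)
fastTiming <- function(fs = 64) trialTiming(fs = fs)

# session of noisy sinusoids on electrode A: one row per trial with its own
# amplitude; electrode B carries independent low-level noise
sineSession <- function(amps, labels, fs = 64, freq = 11, noiseSd = 0.01,
                        seed = 1, imageryGain = NULL) {
  set.seed(seed)
  tm <- fastTiming(fs)
  nS <- round(tm@trialEnd * fs)
  t <- (seq_len(nS) - 1) / fs
  n <- length(amps)
  epochs <- array(0, c(n, 2, nS))
  gain <- rep(1, nS)
  for (tr in seq_len(n)) {
    g <- gain
    if (!is.null(imageryGain))
      g[t >= tm@cueOnset] <- imageryGain[tr]
    epochs[tr, 1, ] <- amps[tr] * g * sin(2 * pi * freq * t + runif(1, 0, 2 * pi)) +
      rnorm(nS, sd = noiseSd)
    epochs[tr, 2, ] <- rnorm(nS, sd = noiseSd)
  }
  epochedSession(epochs, labels, tm, c("A", "B"))
}

# small synthetic generator spec: 4 electrodes in a row, configurable effects
smallSpec <- function(seed = 1, classes = c("Hand", "Word"), runs = 2L,
                      tpcpr = 5L, artifactRate = 0, fs = 64,
                      effects = list(), amplitudes = NULL, noiseSd = 5) {
  grid <- electrodeGrid(c("C3", "Cz", "C4", "Pz"),
                        rows = c(1, 1, 1, 2), cols = c(1, 2, 3, 2))
  bands <- defaultBands()
  eff <- array(0, c(length(classes), 4, nrow(bands)),
               dimnames = list(classes, grid@labels, rownames(bands)))
  for (e in effects) eff[e$class, e$electrode, e$band] <- e$value
  amp <- if (is.null(amplitudes)) defaultRhythmAmplitudes(grid, bands)
         else amplitudes
  generatorSpec(grid = grid, timing = trialTiming(fs = fs), classes = classes,
                runs = runs, trialsPerClassPerRun = tpcpr,
                effectMatrix = eff, rhythmAmplitudes = amp,
                noiseSd = noiseSd, artifactRate = artifactRate,
                bands = bands, seed = seed)
}

# default three-derivation sets used by the packaged configurations
autoDerivations <- function(grid = defaultMontage())
  parseDerivations(grid, c("FCz-CPz", "P1-P2", "CP4-PO4"))
smrDerivations <- function(grid = defaultMontage())
  parseDerivations(grid, c("C3-CP3", "FCz-CPz", "CP4-P4"))
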
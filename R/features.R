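#' The default feature bands
#'
#' Five bands in the alpha and beta range whose power is modulated by motor
#' imagery and the non-motor mental tasks used here: 8-10, 10-13, 13-16,
#' 16-24 and 24-30 Hz.
#'
#' @return numeric matrix (5 x 2) of band edges in Hz
#' @export
defaultBands <- function() {
  b <- rbind(c(8, 10), c(10, 13), c(13, 16), c(16, 24), c(24, 30))
  dimnames(b) <- list(paste0(b[, 1], "-", b[, 2], "Hz"), c("low", "high"))
  b
}

# sample indices of a half-open time window [from, to) (trial time 0 = first sample)
.windowIdx <- function(from, to, fs) {
  seq.int(floor(from * fs) + 1L, floor(to * fs))
}

# cached 4th-order Butterworth band-pass coefficients
.filterCache <- new.env(parent = emptyenv())
.butterBand <- function(low, high, fs) {
  key <- sprintf("%g|%g|%g", low, high, fs)
  bf <- .filterCache[[key]]
  if (is.null(bf)) {
    if (low <= 0 || high >= fs / 2)
      stop(sprintf("band %g-%g Hz outside (0, Nyquist = %g Hz)", low, high, fs / 2),
           call. = FALSE)
    bf <- signal::butter(4, c(low, high) / (fs / 2), type = "pass")
    .filterCache[[key]] <- bf
  }
  bf
}

# trailing moving average over w samples; entries before index w are NA
.trailingMean <- function(x, w) {
  cs <- cumsum(x)
  out <- rep(NA_real_, length(x))
  idx <- seq.int(w, length(x))
  out[idx] <- (cs[idx] - c(0, cs)[idx - w + 1L]) / w
  out
}

#' Causal logarithmic band-power time course
#'
#' Band-pass filters a signal with a causal 4th-order Butterworth filter,
#' squares the samples, applies a trailing (past-only) moving average over
#' `avgWindow` seconds and takes the natural log. The first `avgWindow`
#' seconds are the warm-up and are returned as `NA`. Averaged power is
#' floored at 1e-10 before the log so silent input cannot produce `-Inf`.
#'
#' @param x single-channel signal in microvolts.
#' @param band numeric length-2, band edges in Hz.
#' @param fs sampling rate in Hz.
#' @param avgWindow averaging window in seconds (default 1).
#' @return numeric vector of log band power (log microvolt^2), `NA` during
#'   warm-up, with attribute `validFrom` (seconds)
#' @examples
#' fs <- 256
#' t <- seq(0, 4 - 1 / fs, by = 1 / fs)
#' bp <- bandpowerTimecourse(2 * sin(2 * pi * 9 * t), c(8, 10), fs)
#' mean(bp[700:1024])  # ~ log(2^2 / 2)
#' @export
bandpowerTimecourse <- function(x, band, fs, avgWindow = 1) {
  w <- round(avgWindow * fs)
  stopifnot(length(x) >= w)
  bf <- .butterBand(band[1], band[2], fs)
  filt <- signal::filter(bf, x)
  p <- .trailingMean(as.numeric(filt)^2, w)
  out <- log(pmax(p, 1e-10))
  attr(out, "validFrom") <- avgWindow
  out
}

#' Log band-power feature array of an epoched session
#'
#' Computes the causal log band-power time course of every derivation x band
#' combination for every trial. Feature order is derivation-major: all bands
#' of derivation 1, then derivation 2, and so on.
#'
#' @param session an [EpochedSession-class].
#' @param derivations list of [BipolarDerivation-class].
#' @param bands numeric matrix (n x 2) of band edges in Hz.
#' @param avgWindow averaging window in seconds.
#' @return list with `values` (trials x features x samples array, `NA` during
#'   warm-up), `index` (data.frame `derivation`, `derivationIndex`, `band`),
#'   and `validFrom` (seconds)
#' @export
computeFeatures <- function(session, derivations, bands = defaultBands(),
                            avgWindow = 1) {
  fs <- session@timing@fs
  dsig <- derivationSignals(session, derivations)
  nT <- dim(dsig)[1L]; nD <- dim(dsig)[2L]; nS <- dim(dsig)[3L]
  nB <- nrow(bands)
  vals <- array(NA_real_, c(nT, nD * nB, nS))
  for (d in seq_len(nD)) {
    for (b in seq_len(nB)) {
      f <- (d - 1L) * nB + b
      for (tr in seq_len(nT))
        vals[tr, f, ] <- bandpowerTimecourse(dsig[tr, d, ], bands[b, ], fs, avgWindow)
    }
  }
  index <- data.frame(
    derivation = rep(vapply(derivations, derivationLabel, ""), each = nB),
    derivationIndex = rep(seq_len(nD), each = nB),
    band = rep.int(seq_len(nB), nD))
  list(values = vals, index = index, validFrom = avgWindow)
}

#' Fisher-criterion separability of two sample vectors
#'
#' `(mean(x1) - mean(x2))^2 / (var(x1) + var(x2) + eps)`. Nonnegative,
#' symmetric in its arguments, and invariant to adding a common constant.
#'
#' @param x1,x2 numeric vectors (length >= 2 each for a meaningful variance).
#' @param eps stabilizer added to the variance sum (default 1e-12).
#' @return nonnegative scalar
#' @examples
#' fisherScore(rnorm(100), rnorm(100, mean = 2))
#' @export
fisherScore <- function(x1, x2, eps = 1e-12) {
  (mean(x1) - mean(x2))^2 / (var(x1) + var(x2) + eps)
}

# per-trial mean of a feature time course over a half-open window, NA-safe
.windowMeans <- function(values, idx) {
  # values: trials x features x samples; returns trials x features
  sub <- values[, , idx, drop = FALSE]
  apply(sub, c(1L, 2L), mean)
}

#' Select the most separable band of one derivation
#'
#' Pools each trial's mean feature value over the analysis window, computes
#' the Fisher score between the two classes for every band, and returns the
#' best band. Exact ties go to the lowest band index (lowest frequency).
#'
#' @param values trials x bands x samples array of log band-power features of
#'   one derivation (as produced by [computeFeatures()] for a single
#'   derivation).
#' @param labels per-trial class labels; exactly two classes must be present,
#'   each with at least one trial.
#' @param fs sampling rate in Hz.
#' @param window numeric length-2, analysis window `[start, end)` in seconds
#'   (default `c(4, 8)`).
#' @return list with `band` (index), `score`, and `scores` (all bands)
#' @export
selectBestBand <- function(values, labels, fs, window = c(4, 8)) {
  classes <- sort(unique(labels))
  if (length(classes) != 2L)
    stop("exactly two classes required for band selection", call. = FALSE)
  if (any(tabulate(factor(labels, classes)) == 0L))
    stop("both classes need at least one trial", call. = FALSE)
  idx <- .windowIdx(window[1], window[2], fs)
  wm <- .windowMeans(values, idx)          # trials x bands
  g1 <- labels == classes[1]
  scores <- vapply(seq_len(ncol(wm)), function(b)
    fisherScore(wm[g1, b], wm[!g1, b]), 0)
  best <- which.max(scores)                # which.max takes the first on ties
  list(band = best, score = scores[best], scores = scores)
}
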
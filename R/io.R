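.padField <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  sprintf(sprintf("%%-%ds", width), x)
}

#' Write a continuous multichannel recording as EDF
#'
#' Minimal EDF (16-bit) writer for continuous microvolt recordings: one-second
#' data records, per-signal physical scaling derived from the data. The
#' recording is truncated to whole seconds (with a warning) because EDF
#' stores fixed-length records.
#'
#' @param x channels x samples numeric matrix (microvolts) with channel row
#'   names.
#' @param fs sampling rate in Hz (samples per record).
#' @param path output file path.
#' @return the path, invisibly
#' @export
writeEDF <- function(x, fs, path) {
  nCh <- nrow(x)
  nRec <- floor(ncol(x) / fs)
  if (nRec * fs < ncol(x)) {
    warning("recording truncated to whole seconds for EDF records")
    x <- x[, seq_len(nRec * fs), drop = FALSE]
  }
  labels <- rownames(x) %||% paste0("Ch", seq_len(nCh))
  physMax <- pmax(apply(abs(x), 1L, max), 1e-6)
  physMin <- -physMax
  digMax <- 32767; digMin <- -32768

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  wr(.padField("0", 8))
  wr(.padField("synthetic subject", 80))
  wr(.padField("adbci recording", 80))
  wr("01.01.20"); wr("00.00.00")
  wr(.padField(256 + 256 * nCh, 8))
  wr(.padField("", 44))
  wr(.padField(nRec, 8))
  wr(.padField(1, 8))
  wr(.padField(nCh, 4))
  for (f in list(function(i) .padField(labels[i], 16),
                 function(i) .padField("", 80),
                 function(i) .padField("uV", 8),
                 function(i) .padField(sprintf("%.8g", physMin[i]), 8),
                 function(i) .padField(sprintf("%.8g", physMax[i]), 8),
                 function(i) .padField(digMin, 8),
                 function(i) .padField(digMax, 8),
                 function(i) .padField("", 80),
                 function(i) .padField(fs, 8),
                 function(i) .padField("", 32)))
    for (i in seq_len(nCh)) wr(f(i))

  scale <- (digMax - digMin) / (physMax - physMin)
  for (r in seq_len(nRec)) {
    idx <- (r - 1L) * fs + seq_len(fs)
    for (i in seq_len(nCh)) {
      dig <- round((x[i, idx] - physMin[i]) * scale[i] + digMin)
      writeBin(as.integer(pmin(pmax(dig, digMin), digMax)), con,
               size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read a continuous EDF recording
#'
#' Counterpart of [writeEDF()]: reads 16-bit continuous EDF and rescales to
#' physical units. All signals must share one sampling rate.
#'
#' @param path EDF file path.
#' @return list with `signal` (channels x samples matrix, labelled rows),
#'   `fs` (Hz), and `labels`
#' @export
readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                      # header bytes
  rd(44)
  nRec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  nCh <- as.integer(rd(4))
  fields <- list(label = 16, transducer = 80, dim = 8, physMin = 8, physMax = 8,
                 digMin = 8, digMax = 8, prefilter = 80, nSamp = 8, reserved = 32)
  hdr <- lapply(fields, function(w) vapply(seq_len(nCh), function(i) rd(w), ""))
  physMin <- as.numeric(hdr$physMin); physMax <- as.numeric(hdr$physMax)
  digMin <- as.numeric(hdr$digMin); digMax <- as.numeric(hdr$digMax)
  nSamp <- as.integer(hdr$nSamp)
  if (length(unique(nSamp)) != 1L)
    stop("signals with differing sampling rates are not supported", call. = FALSE)
  fs <- nSamp[1] / recDur
  out <- matrix(0, nCh, nRec * nSamp[1],
                dimnames = list(hdr$label, NULL))
  for (r in seq_len(nRec)) {
    for (i in seq_len(nCh)) {
      dig <- readBin(con, "integer", n = nSamp[i], size = 2L,
                     endian = "little", signed = TRUE)
      idx <- (r - 1L) * nSamp[i] + seq_len(nSamp[i])
      out[i, idx] <- (dig - digMin[i]) / (digMax[i] - digMin[i]) *
        (physMax[i] - physMin[i]) + physMin[i]
    }
  }
  list(signal = out, fs = fs, labels = unname(hdr$label))
}

#' Read or write a cue event table
#'
#' Tab-separated file with columns `onset` (seconds) and `label`.
#'
#' @param path file path.
#' @return [readEvents()] returns a data.frame with `onset` and `label`
#' @export
readEvents <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("onset", "label") %in% names(ev)))
  ev[, c("onset", "label")]
}

#' @rdname readEvents
#' @param events data.frame with columns `onset` and `label`.
#' @export
writeEvents <- function(events, path) {
  utils::write.table(events[, c("onset", "label")], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize an epoched session
#'
#' Run-time serialization of an [EpochedSession-class] (RDS container).
#'
#' @param session an [EpochedSession-class].
#' @param path file path.
#' @return the path, invisibly
#' @export
writeEpochedSession <- function(session, path) {
  saveRDS(list(epochs = session@epochs, labels = session@labels,
               timing = list(relaxStart = session@timing@relaxStart,
                             relaxEnd = session@timing@relaxEnd,
                             cueOnset = session@timing@cueOnset,
                             imageryEndAnalysis = session@timing@imageryEndAnalysis,
                             trialEnd = session@timing@trialEnd,
                             fs = session@timing@fs),
               channelLabels = session@channelLabels,
               artifactFlags = session@artifactFlags,
               rejectionLog = session@rejectionLog),
          path)
  invisible(path)
}

#' @rdname writeEpochedSession
#' @export
readEpochedSession <- function(path) {
  x <- readRDS(path)
  s <- epochedSession(x$epochs, x$labels, do.call(trialTiming, x$timing),
                      x$channelLabels)
  s@artifactFlags <- x$artifactFlags
  s@rejectionLog <- x$rejectionLog
  s
}
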
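#' Construct an electrode grid
#'
#' @param labels character vector of electrode names.
#' @param rows,cols integer grid coordinates, one per label. Rows are coronal
#'   lines numbered front to back, columns sagittal lines numbered left to
#'   right.
#' @return an [ElectrodeGrid-class]
#' @examples
#' g <- electrodeGrid(c("C3", "Cz", "C4"), rows = c(1, 1, 1), cols = c(1, 2, 3))
#' @export
electrodeGrid <- function(labels, rows, cols) {
  coords <- cbind(row = as.integer(rows), col = as.integer(cols))
  rownames(coords) <- labels
  new("ElectrodeGrid", labels = as.character(labels), coords = coords)
}

#' Default 30-channel montage
#'
#' A 30-electrode 10/20-style grid over frontal to parieto-occipital coronal
#' lines, including the lateral temporal/parietal sites (T3, T4, P7, P8) that
#' clinical recordings typically carry. It approximates the montage commonly
#' used for three-bipolar-derivation ERD interfaces; positions are plain
#' integer grid coordinates, not head geometry.
#'
#' @return an [ElectrodeGrid-class] with 30 electrodes
#' @export
defaultMontage <- function() {
  defs <- list(
    # row 1: frontal
    c("F3", 1, 3), c("Fz", 1, 5), c("F4", 1, 7),
    # row 2: fronto-central
    c("FC3", 2, 3), c("FC1", 2, 4), c("FCz", 2, 5), c("FC2", 2, 6), c("FC4", 2, 7),
    # row 3: central
    c("T3", 3, 1), c("C3", 3, 3), c("C1", 3, 4), c("Cz", 3, 5),
    c("C2", 3, 6), c("C4", 3, 7), c("T4", 3, 9),
    # row 4: centro-parietal
    c("CP3", 4, 3), c("CP1", 4, 4), c("CPz", 4, 5), c("CP2", 4, 6), c("CP4", 4, 7),
    # row 5: parietal
    c("P7", 5, 1), c("P3", 5, 3), c("P1", 5, 4), c("Pz", 5, 5),
    c("P2", 5, 6), c("P4", 5, 7), c("P8", 5, 9),
    # row 6: parieto-occipital
    c("PO3", 6, 3), c("POz", 6, 5), c("PO4", 6, 7))
  electrodeGrid(vapply(defs, `[`, "", 1L),
                as.integer(vapply(defs, `[`, "", 2L)),
                as.integer(vapply(defs, `[`, "", 3L)))
}

.gridPos <- function(grid, label) {
  i <- match(label, grid@labels)
  if (is.na(i))
    stop(sprintf("electrode '%s' is not in the montage", label), call. = FALSE)
  grid@coords[i, ]
}

#' Construct a bipolar derivation between two grid electrodes
#'
#' The two electrodes must share a grid row (coronal orientation) or column
#' (sagittal orientation). The covered area is the inclusive set of grid
#' positions from anode to cathode; intermediate positions need not hold an
#' electrode.
#'
#' @param grid an [ElectrodeGrid-class].
#' @param anode,cathode electrode labels; output signal is anode - cathode.
#' @return a [BipolarDerivation-class]
#' @examples
#' d <- bipolarDerivation(defaultMontage(), "FCz", "CPz")
#' @export
bipolarDerivation <- function(grid, anode, cathode) {
  pa <- .gridPos(grid, anode)
  pc <- .gridPos(grid, cathode)
  if (pa[1] == pc[1] && pa[2] != pc[2]) {
    orientation <- "coronal"
    cols <- seq(pa[2], pc[2])
    covered <- cbind(row = rep(pa[1], length(cols)), col = cols)
  } else if (pa[2] == pc[2] && pa[1] != pc[1]) {
    orientation <- "sagittal"
    rows <- seq(pa[1], pc[1])
    covered <- cbind(row = rows, col = rep(pa[2], length(rows)))
  } else {
    stop(sprintf("electrodes %s and %s do not share a grid line", anode, cathode),
         call. = FALSE)
  }
  new("BipolarDerivation", anode = anode, cathode = cathode,
      orientation = orientation, gap = nrow(covered) - 2L,
      covered = covered)
}

#' Label of a bipolar derivation
#' @param d a [BipolarDerivation-class]
#' @return character, e.g. `"FCz-CPz"`
#' @export
derivationLabel <- function(d) paste0(d@anode, "-", d@cathode)

#' Resolve derivation labels against a montage
#'
#' @param grid an [ElectrodeGrid-class].
#' @param labels character vector like `c("FCz-CPz", "P1-P2")`.
#' @return list of [BipolarDerivation-class]
#' @export
parseDerivations <- function(grid, labels) {
  lapply(labels, function(lab) {
    parts <- strsplit(lab, "-", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop(sprintf("cannot parse derivation label '%s'", lab), call. = FALSE)
    bipolarDerivation(grid, parts[1], parts[2])
  })
}

#' Enumerate all bipolar derivations of a montage
#'
#' Returns every canonically oriented electrode pair lying on a common grid
#' line and separated by at most `maxGap + 1` grid steps. Canonical polarity
#' is anterior minus posterior (sagittal) and left minus right (coronal).
#' Skipped intermediate positions need not hold an electrode unless
#' `requireOccupiedGaps = TRUE`.
#'
#' @param grid an [ElectrodeGrid-class].
#' @param maxGap maximum number of skipped grid positions (default 1).
#' @param requireOccupiedGaps if `TRUE`, every skipped position must hold an
#'   electrode.
#' @return list of [BipolarDerivation-class], no duplicates
#' @examples
#' length(enumerateDerivations(defaultMontage()))
#' @export
enumerateDerivations <- function(grid, maxGap = 1L, requireOccupiedGaps = FALSE) {
  stopifnot(maxGap >= 0, length(grid@labels) >= 1L)
  coords <- grid@coords
  out <- list()
  n <- length(grid@labels)
  if (n < 2L) return(out)
  occupied <- paste(coords[, 1], coords[, 2])
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      pi <- coords[i, ]; pj <- coords[j, ]
      sameRow <- pi[1] == pj[1]; sameCol <- pi[2] == pj[2]
      if (!sameRow && !sameCol) next
      steps <- if (sameRow) abs(pi[2] - pj[2]) else abs(pi[1] - pj[1])
      if (steps > maxGap + 1L) next
      # canonical polarity: smaller coordinate first (anterior / left)
      first <- if (sameRow) {
        if (pi[2] < pj[2]) i else j
      } else {
        if (pi[1] < pj[1]) i else j
      }
      second <- if (first == i) j else i
      d <- bipolarDerivation(grid, grid@labels[first], grid@labels[second])
      if (requireOccupiedGaps && d@gap > 0L) {
        inner <- d@covered[-c(1L, nrow(d@covered)), , drop = FALSE]
        if (!all(paste(inner[, 1], inner[, 2]) %in% occupied)) next
      }
      out[[length(out) + 1L]] <- d
    }
  }
  out
}

#' Do two bipolar derivations overlap on the scalp?
#'
#' Two derivations overlap iff their covered grid-position sets intersect.
#' The predicate is symmetric and reflexive; the greedy channel selection
#' of [selectChannels()] uses it to keep only non-overlapping derivations.
#'
#' @param d1,d2 [BipolarDerivation-class] objects on the same grid.
#' @return logical
#' @export
derivationsOverlap <- function(d1, d2) {
  k1 <- paste(d1@covered[, 1], d1@covered[, 2])
  k2 <- paste(d2@covered[, 1], d2@covered[, 2])
  any(k1 %in% k2)
}

#' Apply a bipolar derivation to a recording
#'
#' Computes the sample-aligned difference signal anode minus cathode.
#'
#' @param x a channels x samples numeric matrix with electrode row names, or
#'   an [EpochedSession-class].
#' @param d a [BipolarDerivation-class].
#' @return for a matrix, a numeric vector; for an epoched session, a
#'   trials x samples matrix
#' @export
setGeneric("applyDerivation", function(x, d) standardGeneric("applyDerivation"))

#' @rdname applyDerivation
setMethod("applyDerivation", "matrix", function(x, d) {
  for (lab in c(d@anode, d@cathode))
    if (!lab %in% rownames(x))
      stop(sprintf("channel '%s' missing from recording", lab), call. = FALSE)
  x[d@anode, ] - x[d@cathode, ]
})

#' @rdname applyDerivation
setMethod("applyDerivation", "EpochedSession", function(x, d) {
  ia <- match(d@anode, x@channelLabels)
  ic <- match(d@cathode, x@channelLabels)
  if (is.na(ia)) stop(sprintf("channel '%s' missing from session", d@anode), call. = FALSE)
  if (is.na(ic)) stop(sprintf("channel '%s' missing from session", d@cathode), call. = FALSE)
  x@epochs[, ia, , drop = TRUE] - x@epochs[, ic, , drop = TRUE]
})

#' Derivation signals of an epoched session
#'
#' @param session an [EpochedSession-class].
#' @param derivations list of [BipolarDerivation-class].
#' @return numeric array trials x derivations x samples
#' @export
derivationSignals <- function(session, derivations) {
  d <- dim(session@epochs)
  out <- array(0, c(d[1L], length(derivations), d[3L]))
  for (k in seq_along(derivations)) {
    sig <- applyDerivation(session, derivations[[k]])
    if (is.null(dim(sig))) sig <- matrix(sig, nrow = 1L)  # single-trial session
    out[, k, ] <- sig
  }
  dimnames(out) <- list(NULL, vapply(derivations, derivationLabel, ""), NULL)
  out
}

#' Read or write a montage configuration
#'
#' Montages are stored as YAML (or JSON): a list of `{label, row, col}`
#' records.
#'
#' @param path file path.
#' @return [readMontage()] returns an [ElectrodeGrid-class].
#' @export
readMontage <- function(path) {
  recs <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  else
    do.call(rbind, lapply(yaml::read_yaml(path), as.data.frame))
  electrodeGrid(recs$label, recs$row, recs$col)
}

#' @rdname readMontage
#' @param grid an [ElectrodeGrid-class] to write.
#' @export
writeMontage <- function(grid, path) {
  recs <- lapply(seq_along(grid@labels), function(i)
    list(label = grid@labels[i],
         row = unname(grid@coords[i, 1]), col = unname(grid@coords[i, 2])))
  yaml::write_yaml(recs, path)
  invisible(path)
}
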
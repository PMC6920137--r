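# 8x3 feature extraction, injection-log verification, balanced
# ground-truth assembly and randomized disjoint train/test splits.

#' Extract the 8 x 3 feature matrix for one candidate bin
#'
#' The classifier input: the eight relative band powers at the
#' candidate bin plus its previous and next bins (columns ordered
#' t-1, t, t+1). The 3-bin context guards against an event split
#' across two adjacent bins. At a segment edge the missing neighbour
#' is replaced by replicating the existing one, preserving the 8 x 3
#' shape.
#'
#' @param rel a [RelativeSpectrogram-class].
#' @param channel channel index.
#' @param bin time-bin index (1-based).
#' @return numeric 8 x 3 matrix.
#' @export
extractFeature <- function(rel, channel, bin) {
  rp <- relPower(rel)
  nT <- dim(rp)[3]
  stopifnot(bin >= 1L, bin <= nT)
  prev <- if (bin > 1L) bin - 1L else bin + 1L
  nxt <- if (bin < nT) bin + 1L else bin - 1L
  if (nT == 1L) prev <- nxt <- bin
  m <- cbind(rp[channel, , prev], rp[channel, , bin], rp[channel, , nxt])
  if (bin == 1L) m[, 1L] <- m[, 2L]          # edge replication
  if (bin == nT) m[, 3L] <- m[, 2L]
  dimnames(m) <- list(rel@bandSet$name, c("prev", "cur", "next"))
  m
}

#' Extract features for a set of candidates
#'
#' Vectorised [extractFeature()] over the rows of a candidate table.
#'
#' @param rel a [RelativeSpectrogram-class].
#' @param candidates data.frame with `channel` and `bin` columns
#'   (e.g. from [detectCandidates()]).
#' @return numeric array 8 x 3 x nrow(candidates).
#' @export
extractFeatures <- function(rel, candidates) {
  rp <- relPower(rel)
  nT <- dim(rp)[3]
  n <- nrow(candidates)
  out <- array(0, dim = c(8L, 3L, n))
  b <- candidates$bin
  prev <- ifelse(b > 1L, b - 1L, b)
  nxt <- ifelse(b < nT, b + 1L, b)
  for (i in seq_len(n)) {
    ch <- candidates$channel[i]
    out[, , i] <- cbind(rp[ch, , prev[i]], rp[ch, , b[i]], rp[ch, , nxt[i]])
  }
  out
}

#' Verify detector candidates against a synthetic injection log
#'
#' Stands in for the visual-verification step when the data are
#' synthetic: an injected event is verified when a candidate bin with
#' the event's true class lies within `binTol` bins of the bin
#' containing the event's midpoint (the closest such bin is kept, so
#' each injection contributes at most one event). Baseline truth is
#' drawn from detector-baseline bins at least `guardS` seconds away
#' from every injection on the same channel.
#'
#' @param candidates output of [detectCandidates()] for one record.
#' @param injectionLog data.frame with `channel`, `onset_s`,
#'   `duration_s`, `class` columns (see [generateSubject()]).
#' @param binDuration bin length in seconds (default 0.25).
#' @param binTol bin tolerance for matching (default 1).
#' @param guardS guard interval for baseline bins (default 1 s).
#' @return list: `events` (verified non-baseline candidate rows with a
#'   `label` column set to the true class), `baseline` (clean baseline
#'   candidate rows), `recovery` (fraction of injections verified).
#' @export
verifyCandidates <- function(candidates, injectionLog, binDuration = 0.25,
                             binTol = 1L, guardS = 1) {
  byChan <- split(seq_len(nrow(candidates)), candidates$channel)
  hitIdx <- integer()
  matched <- logical(nrow(injectionLog))
  for (i in seq_len(nrow(injectionLog))) {
    ev <- injectionLog[i, ]
    midBin <- floor((ev$onset_s + ev$duration_s / 2) / binDuration) + 1L
    ci <- byChan[[as.character(ev$channel)]]
    sel <- ci[abs(candidates$bin[ci] - midBin) <= binTol &
                candidates$label[ci] == ev$class]
    if (length(sel)) {
      hitIdx <- c(hitIdx, sel[which.min(abs(candidates$bin[sel] - midBin))])
      matched[i] <- TRUE
    }
  }
  events <- candidates[unique(hitIdx), ]

  base <- candidates[candidates$label == "baseline", ]
  if (nrow(injectionLog) > 0L && nrow(base) > 0L) {
    maxBin <- max(candidates$bin)
    keep <- logical(nrow(base))
    for (ch in unique(base$channel)) {
      ev <- injectionLog[injectionLog$channel == ch, ]
      blocked <- logical(maxBin)
      for (i in seq_len(nrow(ev))) {
        b0 <- max(1L, floor((ev$onset_s[i] - guardS) / binDuration) + 1L)
        b1 <- min(maxBin, floor((ev$onset_s[i] + ev$duration_s[i] + guardS) /
                                  binDuration) + 1L)
        blocked[b0:b1] <- TRUE
      }
      sel <- base$channel == ch
      keep[sel] <- !blocked[base$bin[sel]]
    }
    base <- base[keep, ]
  }
  list(events = events, baseline = base,
       recovery = if (nrow(injectionLog)) mean(matched) else NA_real_)
}

#' Assemble a balanced ground-truth set
#'
#' Uniform random subsampling without replacement, stratified by
#' (subject, class), across all channels and segments. A class absent
#' for a subject yields an empty cell (flagged, not an error); a cell
#' with fewer than `nPerClass` candidates keeps all of them and is
#' flagged short.
#'
#' @param perSubject named list (one element per subject) of lists
#'   with `rel` (a [RelativeSpectrogram-class]) and `candidates` (a
#'   labelled candidate data.frame whose `label` column is the ground
#'   truth, e.g. the union of `events` and `baseline` from
#'   [verifyCandidates()]).
#' @param nPerClass events per class per subject (default 1000).
#' @param seed RNG seed for the subsampling.
#' @return A [GroundTruthSet-class].
#' @export
assembleGroundTruth <- function(perSubject, nPerClass = 1000L, seed = 1L) {
  set.seed(seed)
  feats <- list(); infos <- list()
  for (sj in names(perSubject)) {
    cand <- perSubject[[sj]]$candidates
    rel <- perSubject[[sj]]$rel
    for (cl in eventClasses()) {
      rows <- cand[cand$label == cl, , drop = FALSE]
      if (nrow(rows) == 0L) {
        message("assembleGroundTruth: no '", cl, "' events for ", sj)
        next
      }
      if (nrow(rows) > nPerClass)
        rows <- rows[sample.int(nrow(rows), nPerClass), , drop = FALSE]
      else if (nrow(rows) < nPerClass)
        message(sprintf("assembleGroundTruth: %s/%s short (%d < %d)",
                        sj, cl, nrow(rows), nPerClass))
      feats[[length(feats) + 1L]] <- extractFeatures(rel, rows)
      infos[[length(infos) + 1L]] <- data.frame(
        subject = sj, channel = rows$channel, bin = rows$bin,
        time_s = rows$time_s, label = cl, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(feats)) stop("no events to assemble")
  info <- do.call(rbind, infos)
  info$label <- factor(info$label, levels = eventClasses())
  new("GroundTruthSet",
      features = array(unlist(feats), dim = c(8L, 3L, nrow(info))),
      info = info)
}

#' Randomized disjoint train/test splits
#'
#' For each randomization and each (subject, class) cell, draws
#' `nTrain` training and `nTest` test events uniformly without
#' replacement, disjoint within the cell. Deterministic given `seed`.
#'
#' @param gt a [GroundTruthSet-class].
#' @param nTrain training events per class per subject (typical
#'   sweep range 50-500).
#' @param nTest test events per class per subject (default 500).
#' @param nRandomizations number of independent splits (default 10).
#' @param seed RNG seed.
#' @return list of length `nRandomizations`; each element has integer
#'   index vectors `train` and `test` into the ground-truth set.
#' @export
makeSplits <- function(gt, nTrain, nTest = 500L, nRandomizations = 10L,
                       seed = 1L) {
  info <- eventInfo(gt)
  cells <- split(seq_len(nrow(info)),
                 list(info$subject, info$label), drop = TRUE)
  short <- vapply(cells, length, 1L) < nTrain + nTest
  if (any(short))
    stop("split error: insufficient events in ",
         paste(names(cells)[short], collapse = ", "))
  set.seed(seed)
  lapply(seq_len(nRandomizations), function(r) {
    tr <- integer(); te <- integer()
    for (cell in cells) {
      pick <- cell[sample.int(length(cell), nTrain + nTest)]
      tr <- c(tr, pick[seq_len(nTrain)])
      te <- c(te, pick[nTrain + seq_len(nTest)])
    }
    list(train = sort(tr), test = sort(te))
  })
}

#' Write a ground-truth set to CSV
#'
#' One row per event: metadata columns then the 24 feature values
#' (`f_<band>_<step>`). A manifest row group records counts.
#'
#' @param gt a [GroundTruthSet-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeGroundTruthCsv <- function(gt, path) {
  f <- eventFeatures(gt)
  flat <- t(apply(f, 3L, as.vector))
  colnames(flat) <- paste0("f_", rep(defaultBandSet()$name, 3L), "_",
                           rep(c("prev", "cur", "next"), each = 8L))
  utils::write.csv(cbind(eventInfo(gt), as.data.frame(flat)), path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a ground-truth set written by [writeGroundTruthCsv()]
#'
#' @param path CSV path.
#' @return A [GroundTruthSet-class].
#' @export
readGroundTruthCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  fcols <- grep("^f_", names(df))
  feats <- array(t(as.matrix(df[, fcols])), dim = c(8L, 3L, nrow(df)))
  info <- df[, setdiff(seq_along(df), fcols)]
  info$label <- factor(info$label, levels = eventClasses())
  new("GroundTruthSet", features = feats, info = info)
}
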
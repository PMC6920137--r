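# Minimal EDF/EDF+ I/O: fixed-layout ASCII header, 16-bit little-endian
# sample records. Covers the subset of the format this package needs
# (equal sampling rate on all channels, one continuous segment).

.edfPad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

.edfNum <- function(x, width) {
  for (d in 7:1) {
    s <- format(signif(x, d), trim = TRUE, scientific = FALSE)
    if (nchar(s) <= width) return(.edfPad(s, width))
  }
  stop("cannot format ", x, " in ", width, " EDF header characters")
}

#' Write an EegRecord to an EDF file
#'
#' Samples are scaled to the full 16-bit digital range of each
#' channel's physical amplitude span, so the quantisation error is at
#' most one least-significant bit of that span. The record duration is
#' 1 s; a trailing partial second is zero-padded (and noted in the
#' processing log on re-read).
#'
#' @param record an [EegRecord-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readEDF()]
#' @export
writeEDF <- function(record, path) {
  stopifnot(is(record, "EegRecord"))
  x <- samples(record)
  fs <- samplingRate(record)
  if (fs != round(fs)) stop("writeEDF requires an integer sampling rate")
  nc <- nrow(x)
  spr <- as.integer(fs)            # samples per 1 s data record
  nrec <- ceiling(ncol(x) / spr)
  if (ncol(x) < nrec * spr)        # zero-pad final record
    x <- cbind(x, matrix(0, nc, nrec * spr - ncol(x)))

  physMax <- apply(abs(x), 1L, max)
  physMax <- ifelse(physMax > 0, physMax * 1.0001, 1)
  physMaxStr <- vapply(physMax, .edfNum, "", width = 8L)
  # scale with the value as stored in the header so read-back is exact
  physMax <- as.numeric(physMaxStr)   # margin 1e-4 >> rounding error 5e-6
  digMax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edfPad("0", 8L),
    .edfPad(subjectId(record), 80L),
    .edfPad("hfoLSTM synthetic iEEG", 80L),
    .edfPad("01.01.00", 8L), .edfPad("00.00.00", 8L),
    .edfPad(256L * (1L + nc), 8L),
    .edfPad("", 44L),
    .edfPad(nrec, 8L), .edfPad(1L, 8L), .edfPad(nc, 4L)
  )
  sigHdr <- paste0(
    paste(vapply(channelLabels(record), .edfPad, "", width = 16L), collapse = ""),
    paste(rep(.edfPad("", 80L), nc), collapse = ""),
    paste(rep(.edfPad("uV", 8L), nc), collapse = ""),
    paste(vapply(-physMax, .edfNum, "", width = 8L), collapse = ""),
    paste(vapply(physMax, .edfNum, "", width = 8L), collapse = ""),
    paste(rep(.edfPad(-digMax, 8L), nc), collapse = ""),
    paste(rep(.edfPad(digMax, 8L), nc), collapse = ""),
    paste(rep(.edfPad("", 80L), nc), collapse = ""),
    paste(rep(.edfPad(spr, 8L), nc), collapse = ""),
    paste(rep(.edfPad("", 32L), nc), collapse = "")
  )
  writeChar(paste0(hdr, sigHdr), con, eos = NULL, useBytes = TRUE)

  scale <- digMax / physMax
  for (r in seq_len(nrec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    dig <- round(x[, idx, drop = FALSE] * scale)  # nc x spr
    writeBin(as.integer(t(dig)), con, size = 2L, endian = "little")
  }
  invisible(path)
}

.edfReadField <- function(raw, offset, width) {
  trimws(rawToChar(raw[(offset + 1L):(offset + width)]))
}

#' Read an EDF/EDF+ file into an EegRecord
#'
#' Reads the header and all data records, converts digital values back
#' to physical units, and drops any channels named in `exclude` (the
#' user-supplied bad-channel list). All channels must share one
#' sampling rate, which must be at least 500 Hz.
#'
#' @param path path to an EDF/EDF+ file.
#' @param exclude character vector of channel labels to drop.
#' @param subjectId optional subject id; defaults to the header's
#'   patient field (or the file name if empty).
#' @return An [EegRecord-class].
#' @export
readEDF <- function(path, exclude = character(), subjectId = NULL) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 256) stop("EDF format error: file missing or too short")
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 256L)
  headerBytes <- suppressWarnings(as.integer(.edfReadField(hdr, 184L, 8L)))
  nrec <- suppressWarnings(as.integer(.edfReadField(hdr, 236L, 8L)))
  recDur <- suppressWarnings(as.numeric(.edfReadField(hdr, 244L, 8L)))
  nc <- suppressWarnings(as.integer(.edfReadField(hdr, 252L, 4L)))
  patient <- .edfReadField(hdr, 8L, 80L)
  if (anyNA(c(headerBytes, nrec, recDur, nc)) || nc < 1L)
    stop("EDF format error: malformed header")

  sig <- readBin(con, "raw", headerBytes - 256L)
  if (length(sig) < headerBytes - 256L)
    stop("EDF format error: truncated signal header")
  fieldW <- c(label = 16L, transducer = 80L, dim = 8L, physMin = 8L,
              physMax = 8L, digMin = 8L, digMax = 8L, prefilter = 80L,
              spr = 8L, reserved = 32L)
  off <- 0L
  fields <- list()
  for (f in names(fieldW)) {
    w <- fieldW[[f]]
    fields[[f]] <- vapply(seq_len(nc) - 1L, function(i)
      .edfReadField(sig, off + i * w, w), "")
    off <- off + nc * w
  }
  spr <- as.integer(fields$spr)
  physMin <- as.numeric(fields$physMin); physMax <- as.numeric(fields$physMax)
  digMin <- as.numeric(fields$digMin); digMax <- as.numeric(fields$digMax)
  if (length(unique(spr)) != 1L)
    stop("EDF format error: channels with differing sampling rates unsupported")
  fs <- spr[1L] / recDur
  if (fs < 500) stop("sampling-rate error: fs < 500 Hz")

  expected <- nrec * sum(spr) * 2L
  dat <- readBin(con, "integer", n = nrec * sum(spr), size = 2L,
                 endian = "little")
  if (length(dat) < nrec * sum(spr))
    stop("EDF format error: truncated data records")
  # records are [ch1 spr samples, ch2 spr samples, ...] repeated
  arr <- array(dat, dim = c(spr[1L], nc, nrec))
  x <- matrix(0, nc, spr[1L] * nrec)
  for (ch in seq_len(nc)) x[ch, ] <- as.vector(arr[, ch, ])
  gain <- (physMax - physMin) / (digMax - digMin)
  x <- x * gain + (physMin - digMin * gain)

  keep <- !(fields$label %in% exclude)
  if (!any(keep)) stop("all channels excluded")
  if (is.null(subjectId))
    subjectId <- if (nzchar(patient)) patient else basename(path)
  EegRecord(x[keep, , drop = FALSE], fs = fs,
            channelLabels = fields$label[keep], subjectId = subjectId)
}
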
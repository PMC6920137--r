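# Preprocessing: missing-sample repair, zero-phase highpass (300-order
# FIR, forward-backward) and optional second-order IIR notch (Q = 35).

#' Preprocessing configuration
#'
#' @param hpCutoff highpass cutoff in Hz (default 0.5).
#' @param hpOrder FIR filter order (default 300; must be even so the
#'   symmetric design has integer group delay).
#' @param notchEnabled apply the mains notch filter? Default `FALSE`;
#'   enable when line interference is visible in the record.
#' @param notchFreq notch centre frequency in Hz (default 60, US mains).
#' @param notchQ notch quality factor (default 35).
#' @param maxMissingFrac fraction of missing samples above which a
#'   warning is logged (default 0.1).
#' @return list with class `"PreprocessConfig"`.
#' @export
preprocessConfig <- function(hpCutoff = 0.5, hpOrder = 300L,
                             notchEnabled = FALSE, notchFreq = 60,
                             notchQ = 35, maxMissingFrac = 0.1) {
  stopifnot(hpCutoff > 0, notchQ > 0, hpOrder %% 2L == 0L)
  structure(list(
    hpCutoff = hpCutoff, hpOrder = as.integer(hpOrder),
    notchEnabled = isTRUE(notchEnabled), notchFreq = notchFreq,
    notchQ = notchQ, maxMissingFrac = maxMissingFrac
  ), class = "PreprocessConfig")
}

.appendLog <- function(record, line) {
  record@log <- c(record@log, line)
  record
}

#' Repair missing samples
#'
#' Interior runs of missing (NA / NaN) samples are replaced by linear
#' interpolation between the neighbouring valid samples; missing runs
#' at either end take the nearest valid value. Gaps longer than 1 s
#' are repaired too but flagged in the processing log so the segment
#' can be excluded from analysis. Idempotent.
#'
#' @param record an [EegRecord-class], possibly containing NAs.
#' @param maxMissingFrac warn when the channel-wise missing fraction
#'   exceeds this value (default 0.1).
#' @return The repaired [EegRecord-class]; the processing log records
#'   the number of repaired samples.
#' @export
removeMissing <- function(record, maxMissingFrac = 0.1) {
  x <- samples(record)
  fs <- samplingRate(record)
  nMissing <- 0L
  longGap <- FALSE
  for (ch in seq_len(nrow(x))) {
    bad <- !is.finite(x[ch, ])
    if (!any(bad)) next
    if (all(bad)) stop("channel ", ch, " has no valid samples")
    nMissing <- nMissing + sum(bad)
    r <- rle(bad)
    if (any(r$values & r$lengths > fs)) longGap <- TRUE
    if (mean(bad) > maxMissingFrac)
      warning(sprintf("channel %d: %.1f%% samples missing", ch,
                      100 * mean(bad)))
    x[ch, ] <- stats::approx(which(!bad), x[ch, !bad], xout = seq_along(bad),
                             method = "linear", rule = 2L)$y
  }
  record@samples <- x
  record <- .appendLog(record, sprintf(
    "removeMissing: repaired %d samples; length %d%s", nMissing, ncol(x),
    if (longGap) "; gap > 1 s flagged for exclusion" else ""))
  validObject(record)
  record
}

# Forward-backward application of an FIR filter b (a = 1) using FFT
# convolution with reflection padding; zero phase, output length =
# input length.
.zeroPhaseFir <- function(x, b) {
  nb <- length(b)
  npad <- 3L * nb
  if (length(x) <= npad)
    stop("length error: signal shorter than the filter padding requirement")
  xp <- c(2 * x[1L] - rev(x[2L:(npad + 1L)]), x,
          2 * x[length(x)] - rev(x[(length(x) - npad):(length(x) - 1L)]))
  y <- signal::fftfilt(b, xp)
  y <- rev(signal::fftfilt(b, rev(y)))
  # each causal pass delays by (nb-1)/2 for this symmetric design, but
  # the reverse-filter-reverse construction cancels the delays exactly:
  # total shift is zero, so just strip the padding
  y[(npad + 1L):(npad + length(x))]
}

.designHighpass <- function(cutoff, order, fs) {
  stopifnot(cutoff > 0, cutoff < fs / 2, order %% 2L == 0L)
  # Hamming windowed-sinc lowpass, normalised to exactly unit DC gain,
  # then spectrally inverted; the highpass therefore has an exact null
  # at DC even when the cutoff sits deep inside the transition band
  # (as it does for 0.5 Hz at order 300).
  m <- order / 2
  k <- seq(-m, m)
  fc <- cutoff / fs
  lp <- 2 * fc * .sinc(2 * fc * k) *
    (0.54 + 0.46 * cos(pi * k / m))            # Hamming window
  lp <- lp / sum(lp)
  hp <- -lp
  hp[m + 1L] <- hp[m + 1L] + 1
  hp
}

.sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Zero-phase FIR highpass filter
#'
#' Windowed-sinc (Hamming) FIR highpass applied forward-backward, so
#' the net filter has zero phase and the squared magnitude response of
#' the design. The default (0.5 Hz cutoff, order 300) removes DC and
#' slow drift while leaving physiological frequencies untouched.
#'
#' @param record an [EegRecord-class] without missing samples.
#' @param cutoff cutoff frequency in Hz (default 0.5).
#' @param order FIR order (default 300).
#' @return The filtered [EegRecord-class], same length.
#' @export
highpassZeroPhase <- function(record, cutoff = 0.5, order = 300L) {
  b <- .designHighpass(cutoff, order, samplingRate(record))
  x <- samples(record)
  for (ch in seq_len(nrow(x))) x[ch, ] <- .zeroPhaseFir(x[ch, ], b)
  record@samples <- x
  .appendLog(record, sprintf("highpass %g Hz (FIR order %d, zero phase)",
                             cutoff, order))
}

#' Zero-phase IIR notch filter
#'
#' Second-order IIR notch (constrained biquad with quality factor `q`)
#' applied forward-backward per channel. Used to suppress mains
#' interference when present.
#'
#' @param record an [EegRecord-class].
#' @param freq notch centre frequency in Hz (default 60).
#' @param q quality factor, centre frequency over -3 dB bandwidth
#'   (default 35).
#' @return The filtered [EegRecord-class].
#' @export
notchFilter <- function(record, freq = 60, q = 35) {
  fs <- samplingRate(record)
  stopifnot(freq > 0, freq < fs / 2, q > 0)
  w0 <- 2 * pi * freq / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  x <- samples(record)
  for (ch in seq_len(nrow(x)))
    x[ch, ] <- signal::filtfilt(signal::Arma(b = b, a = a), x[ch, ])
  record@samples <- x
  .appendLog(record, sprintf("notch %g Hz (IIR, Q = %g, zero phase)", freq, q))
}

#' Highpass verification view
#'
#' Zero-phase highpass at `cutoff` (default 100 Hz), the conventional
#' view for inspecting ripples. Note that highpass filtering a sharp
#' spike transient itself produces a brief oscillation (a "false
#' ripple"): this view is for verification only and the detector never
#' uses it, relying on band power in the ripple bands instead.
#'
#' @param record an [EegRecord-class].
#' @param cutoff cutoff frequency in Hz (default 100).
#' @param order FIR order (default 300).
#' @return The filtered [EegRecord-class].
#' @export
highpassView <- function(record, cutoff = 100, order = 300L) {
  highpassZeroPhase(record, cutoff = cutoff, order = order)
}

#' Run the standard preprocessing chain
#'
#' Missing-sample repair, zero-phase highpass, and (if enabled) the
#' mains notch, in that order.
#'
#' @param record an [EegRecord-class].
#' @param config a [preprocessConfig()].
#' @return The preprocessed [EegRecord-class].
#' @export
preprocessRecord <- function(record, config = preprocessConfig()) {
  record <- removeMissing(record, config$maxMissingFrac)
  record <- highpassZeroPhase(record, config$hpCutoff, config$hpOrder)
  if (config$notchEnabled)
    record <- notchFilter(record, config$notchFreq, config$notchQ)
  record
}
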
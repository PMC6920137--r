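# Short-time power spectrogram and eight-band averaging.

#' Short-time power spectrogram
#'
#' Power spectrogram from non-overlapping, left-aligned Hann-tapered
#' windows of `windowS` seconds (default 0.25 s, i.e. a 4 Hz frequency
#' grid at any sampling rate: grid step = 1/windowS). A trailing
#' partial window is dropped.
#'
#' One-sided power at grid frequency k/windowS is
#' `c_k |X_k|^2 / (N sum(w^2))` with `c_k = 2` except at DC and
#' Nyquist, so that summing over the grid reproduces the tapered
#' window's mean square divided by the window's mean square (a
#' Parseval identity). The detector only ever uses power ratios, so
#' this fixed scaling is a convention, not a tuning knob.
#'
#' @param record an [EegRecord-class] (no missing samples).
#' @param windowS window length in seconds; `windowS * fs` must be an
#'   integer >= 8. Default 0.25.
#' @return list: `power` (channels x nFreq x nBins array), `freq`
#'   (grid in Hz), `binDuration`, `channelLabels`.
#' @export
stftPower <- function(record, windowS = 0.25) {
  fs <- samplingRate(record)
  n <- windowS * fs
  if (abs(n - round(n)) > 1e-9 || round(n) < 8)
    stop("windowS * fs must be an integer >= 8")
  n <- as.integer(round(n))
  x <- samples(record)
  nBins <- floor(ncol(x) / n)
  if (nBins < 1L) stop("length error: record shorter than one window")

  # periodic Hann taper: exact spectral nulls at all nonadjacent grid
  # frequencies, so grid-aligned tones (e.g. 60 Hz mains) do not leak
  # across bands
  w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1L)) / n))
  nf <- n %/% 2L + 1L
  scale <- rep(2, nf) / (n * sum(w^2))
  scale[1L] <- 1 / (n * sum(w^2))
  if (n %% 2L == 0L) scale[nf] <- 1 / (n * sum(w^2))

  pw <- array(0, dim = c(nrow(x), nf, nBins))
  for (ch in seq_len(nrow(x))) {
    seg <- matrix(x[ch, seq_len(n * nBins)], nrow = n) * w
    ft <- stats::mvfft(seg)[seq_len(nf), , drop = FALSE]
    pw[ch, , ] <- Mod(ft)^2 * scale
  }
  list(power = pw, freq = (seq_len(nf) - 1L) / windowS,
       binDuration = windowS, channelLabels = channelLabels(record))
}

#' Average a spectrogram into the eight spectral bands
#'
#' For each band, the mean of the power values at frequency-grid
#' points falling in the half-open interval `[low, high)`. With the
#' default 4 Hz grid the mains-related frequencies 60, 120, 180 and
#' 200 Hz fall in inter-band gaps and contribute to no band. Grid
#' points within `guardHz` of an interference frequency are excluded
#' as well: the Hann taper's main lobe spreads a tone into its
#' adjacent grid bins, so a band edge one grid step from an
#' interference line (e.g. 64 Hz next to 60 Hz) would otherwise pick
#' up leaked mains power, defeating the purpose of the gaps.
#'
#' @param spec output of [stftPower()].
#' @param bands band definition, default [defaultBandSet()].
#' @param t0 start time (s) of the first bin.
#' @param interferenceFreqs mains frequencies (and harmonics) to guard
#'   against; `NULL` disables the guard.
#' @param guardHz half-width of the guard around each interference
#'   frequency (default 4, one grid step).
#' @return A [BandSpectrogram-class].
#' @export
bandAverage <- function(spec, bands = defaultBandSet(), t0 = 0,
                        interferenceFreqs = c(60, 120, 180, 200),
                        guardHz = 4) {
  .checkBandSet(bands)
  if (max(spec$freq) < max(bands$high) - 1e-9)
    stop("configuration error: frequency grid does not cover the band set")
  guarded <- rep(FALSE, length(spec$freq))
  for (fI in interferenceFreqs)
    guarded <- guarded | abs(spec$freq - fI) <= guardHz + 1e-9
  nb <- nrow(bands)
  d <- dim(spec$power)
  out <- array(0, dim = c(d[1], nb, d[3]))
  for (b in seq_len(nb)) {
    sel <- spec$freq >= bands$low[b] & spec$freq < bands$high[b] & !guarded
    if (!any(sel))
      stop("configuration error: no frequency-grid points in band ",
           bands$name[b])
    out[, b, ] <- apply(spec$power[, sel, , drop = FALSE], c(1, 3), mean)
  }
  new("BandSpectrogram", power = out, binDuration = spec$binDuration,
      bandSet = bands, t0 = t0,
      channelLabels = spec$channelLabels)
}

#' Band spectrogram of a record in one step
#'
#' Convenience wrapper: [stftPower()] followed by [bandAverage()].
#'
#' @inheritParams stftPower
#' @inheritParams bandAverage
#' @return A [BandSpectrogram-class].
#' @export
bandSpectrogram <- function(record, windowS = 0.25,
                            bands = defaultBandSet(), t0 = 0) {
  bandAverage(stftPower(record, windowS), bands = bands, t0 = t0)
}
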
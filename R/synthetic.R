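# Synthetic multichannel iEEG: 1/f^alpha background with injected
# spikes, ripple bursts and ripples-on-spikes, per-subject morphology
# jitter, and an injection log that serves as ground truth.

#' Synthetic iEEG specification
#'
#' Defaults emulate interictal intracranial EEG as the detector
#' expects it: 1/f background (alpha = 1) at 20 uV RMS, biphasic
#' spikes of 20-70 ms at 8-12x the background SD, Hann-enveloped
#' ripple bursts of 4-8 cycles at in-band frequencies (124-250 Hz
#' inside the rip1/rip2/rip3 passbands) at 4-6x SD, and RonS as a
#' spike with a simultaneous ripple centred on the spike peak. Events
#' are scheduled non-overlapping with at least 1 s separation so each
#' 0.25 s bin has a unique true label; background occupies well over
#' 80% of the record, matching the working assumption of the
#' mode-based baseline estimator. Inter-subject variability is
#' log-normal multiplicative jitter on amplitude, duration and ripple
#' frequency.
#'
#' @param nChannels channels per subject (default 4).
#' @param fs sampling rate, Hz (default 500).
#' @param segmentDuration seconds per subject record (default 600).
#' @param alpha background spectral exponent, in `[0.5, 2]`.
#' @param rmsUv background RMS in microvolts.
#' @param spikeAmpRange spike peak amplitude, multiples of background
#'   SD.
#' @param spikeDurRangeMs spike duration range, ms (within 20-70).
#' @param rippleFreqRange ripple centre-frequency range, Hz; draws are
#'   restricted to the rip1/rip2/rip3 passbands inside this range.
#' @param rippleCycleRange cycles per ripple burst (minimum 4; a
#'   ripple must contain more than 3 oscillations).
#' @param rippleAmpRange ripple peak amplitude, multiples of SD.
#' @param ratesPerMin named events-per-minute-per-channel for spike,
#'   rons, ripple (default 2 each).
#' @param scheduling `"poisson"` (counts Poisson-distributed, the
#'   default) or `"exact"` (counts = rate x duration).
#' @param lineNoiseAmp amplitude (uV) of optional 60 Hz mains
#'   interference (default 0 = off).
#' @param morphologySigma sdlog of the per-subject log-normal jitter
#'   on amplitude, duration and ripple frequency (default 0.2).
#' @param minSeparation minimum separation between scheduled event
#'   onsets, seconds (default 1.5, keeping >= 1 s gaps after bin
#'   snapping).
#' @param binDuration spectrogram bin length the injections are
#'   aligned to, seconds (default 0.25).
#' @param binJitter event midpoints are placed uniformly within this
#'   central fraction of a time bin (default 0.5). The non-overlapping
#'   Hann-tapered spectrogram weighs the edges of a bin down, so an
#'   event straddling a bin boundary is visible in neither bin; since
#'   the detector's semantics (and the ground-truth labels) are
#'   per-bin, events are generated as in-bin events. Set to 1 to
#'   place midpoints anywhere in a bin.
#' @param seed master seed; subject k derives its own stream from it.
#' @return list with class `"SyntheticSpec"`.
#' @export
syntheticSpec <- function(nChannels = 4L, fs = 500, segmentDuration = 600,
                          alpha = 1, rmsUv = 20,
                          spikeAmpRange = c(8, 12),
                          spikeDurRangeMs = c(20, 70),
                          rippleFreqRange = c(124, 250),
                          rippleCycleRange = c(4L, 8L),
                          rippleAmpRange = c(4, 6),
                          ratesPerMin = c(spike = 2, rons = 2, ripple = 2),
                          scheduling = c("poisson", "exact"),
                          lineNoiseAmp = 0, morphologySigma = 0.2,
                          minSeparation = 1.5, binDuration = 0.25,
                          binJitter = 0.5, seed = 1L) {
  stopifnot(alpha >= 0.5, alpha <= 2, segmentDuration >= 10,
            spikeDurRangeMs[1] >= 20, spikeDurRangeMs[2] <= 70,
            rippleCycleRange[1] >= 4L,
            all(c("spike", "rons", "ripple") %in% names(ratesPerMin)))
  structure(list(
    nChannels = as.integer(nChannels), fs = fs,
    segmentDuration = segmentDuration, alpha = alpha, rmsUv = rmsUv,
    spikeAmpRange = spikeAmpRange, spikeDurRangeMs = spikeDurRangeMs,
    rippleFreqRange = rippleFreqRange,
    rippleCycleRange = as.integer(rippleCycleRange),
    rippleAmpRange = rippleAmpRange, ratesPerMin = ratesPerMin,
    scheduling = match.arg(scheduling), lineNoiseAmp = lineNoiseAmp,
    morphologySigma = morphologySigma, minSeparation = minSeparation,
    binDuration = binDuration, binJitter = binJitter,
    seed = as.integer(seed)
  ), class = "SyntheticSpec")
}

#' 1/f^alpha Gaussian background
#'
#' Spectrally shaped Gaussian noise: white noise is filtered in the
#' frequency domain with amplitude proportional to f^(-alpha/2) (DC
#' removed), then rescaled to the target RMS.
#'
#' @param duration seconds (>= 10).
#' @param fs sampling rate, Hz.
#' @param alpha spectral exponent in `[0.5, 2]`.
#' @param rms target RMS (attained exactly by rescaling).
#' @param seed optional RNG seed; omit to draw from the current
#'   stream.
#' @return numeric vector of `round(duration * fs)` samples.
#' @export
makeBackground <- function(duration, fs, alpha = 1, rms = 20, seed = NULL) {
  stopifnot(alpha >= 0.5, alpha <= 2, duration >= 10)
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration * fs)
  w <- stats::rnorm(n)
  f <- seq_len(n) - 1
  f <- pmin(f, n - f) * fs / n        # two-sided frequency magnitude
  shape <- c(0, f[-1]^(-alpha / 2))
  x <- Re(stats::fft(stats::fft(w) * shape, inverse = TRUE)) / n
  x * rms / sqrt(mean(x^2))
}

#' Biphasic spike waveform
#'
#' A sharp transient: a fast Gaussian peak followed by a slower
#' opposite deflection (difference of two Gaussians with zero net
#' area), tapered to zero at the snippet ends and mean-corrected with
#' an end-preserving window so the injected snippet has exactly zero
#' mean. Spectral energy concentrates in the beta-gamma range; the
#' smooth shape keeps genuine ripple-band (> 124 Hz) power negligible
#' even though *highpass filtering* such a transient still produces a
#' visible oscillation (the classic "false ripple").
#'
#' @param durationMs spike duration in ms, in `[20, 70]`.
#' @param amplitude peak amplitude (same units as the background, uV).
#' @param fs sampling rate, Hz.
#' @return numeric waveform snippet.
#' @export
makeSpike <- function(durationMs, amplitude, fs) {
  if (durationMs < 20 || durationMs > 70)
    stop("spec error: spike duration must be in [20, 70] ms")
  d <- durationMs / 1000
  # the sharp peak scales with the nominal duration, but the opposite
  # slow deflection keeps a floor width so that even the shortest
  # spikes carry beta-band energy (very brief transients would
  # otherwise be pure gamma)
  dL <- max(d, 0.034)
  n <- max(8L, round(dL * fs))
  t <- (seq_len(n) - 0.5) / n          # normalised time in (0, 1)
  w1 <- exp(-0.5 * ((t - 0.30) / (0.095 * d / dL))^2)
  w2 <- exp(-0.5 * ((t - 0.62) / 0.170)^2)
  s <- w1 - (sum(w1) / sum(w2)) * w2   # zero net area
  edge <- pmin(1, pmin(t, 1 - t) / 0.15)
  s <- s * (0.5 - 0.5 * cos(pi * pmin(edge, 1)))^1  # cosine end taper
  win <- 0.5 - 0.5 * cos(2 * pi * t)
  s <- s - (sum(s) / sum(win)) * win   # exact zero mean, ends stay 0
  if (amplitude == 0) return(s * 0)
  s * amplitude / max(abs(s))
}

.rippleBands <- function() defaultBandSet()[6:8, ]

.inRippleBand <- function(f) {
  rb <- .rippleBands()
  any(f >= rb$low & f < rb$high)
}

#' Hann-enveloped ripple burst
#'
#' `nCycles / centreFreq` seconds of a sinusoid under a Hann envelope.
#' The centre frequency must fall inside one of the ripple passbands
#' (rip1 124-176, rip2 184-196, rip3 204-236 Hz): a burst in an
#' inter-band gap (e.g. 180 Hz) would be invisible to the band set.
#'
#' @param centreFreq burst frequency, Hz.
#' @param nCycles number of oscillation cycles (>= 4; a ripple must
#'   contain more than 3).
#' @param amplitude peak amplitude (uV).
#' @param fs sampling rate, Hz.
#' @return numeric waveform snippet.
#' @export
makeRipple <- function(centreFreq, nCycles, amplitude, fs) {
  if (nCycles < 4)
    stop("spec error: a ripple burst needs more than 3 oscillation cycles")
  if (!.inRippleBand(centreFreq))
    stop("spec error: centre frequency ", centreFreq,
         " Hz lies outside the ripple passbands")
  d <- nCycles / centreFreq
  n <- max(8L, round(d * fs))
  t <- (seq_len(n) - 0.5) / fs
  env <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 0.5) / n)
  s <- env * sin(2 * pi * centreFreq * t)
  if (amplitude == 0) return(s * 0)
  s * amplitude / max(abs(s))
}

# Allowed ripple-frequency intervals: the passbands intersected with
# the requested range, shrunk by an inner margin so a burst's spectral
# main lobe stays mostly inside its band (a burst centred on a band
# edge spills half its energy into the gap).
.rippleFreqIntervals <- function(freqRange) {
  rb <- .rippleBands()
  margin <- pmax(3, 0.15 * (rb$high - rb$low))
  rb$low <- pmax(rb$low, freqRange[1]) + margin
  rb$high <- pmin(rb$high, freqRange[2]) - margin
  rb[rb$low < rb$high, ]
}

# Clamp a jittered ripple frequency into the nearest allowed interval.
.clampRippleFreq <- function(f, freqRange) {
  rb <- .rippleFreqIntervals(freqRange)
  inside <- f >= rb$low & f <= rb$high
  if (any(inside)) return(f)
  i <- which.min(pmin(abs(f - rb$low), abs(f - rb$high)))
  if (abs(f - rb$low[i]) < abs(f - rb$high[i])) rb$low[i] else rb$high[i]
}

# Draw a ripple frequency uniformly over the allowed interval union.
.drawRippleFreq <- function(freqRange) {
  rb <- .rippleFreqIntervals(freqRange)
  wts <- rb$high - rb$low
  i <- sample.int(nrow(rb), 1L, prob = wts)
  stats::runif(1L, rb$low[i], rb$high[i])
}

# Non-overlapping onsets: n sorted uniforms stretched so consecutive
# onsets differ by at least minSep.
.scheduleOnsets <- function(n, duration, minSep, headroom) {
  if (n == 0L) return(numeric())
  slack <- duration - headroom - n * minSep
  if (slack <= 0)
    stop("scheduling error: event rates too high for >= ", minSep,
         " s separation")
  sort(stats::runif(n, 0, slack)) + (seq_len(n) - 1L) * minSep
}

#' Generate one synthetic subject
#'
#' Background plus scheduled, non-overlapping injections of spikes,
#' ripples and RonS on every channel, with this subject's morphology
#' jitter applied, plus optional 60 Hz line interference. Everything
#' is reproducible from `(spec, subjectIndex)`.
#'
#' @param spec a [syntheticSpec()].
#' @param subjectIndex positive integer; selects the subject's RNG
#'   stream and morphology offsets.
#' @param subjectId subject id string (default `"S<subjectIndex>"`).
#' @param classRates optional override of `spec$ratesPerMin` (e.g.
#'   `rons = 0` for a subject without RonS events).
#' @return list: `record` (an [EegRecord-class]), `log` (data.frame
#'   with `subject`, `channel`, `onset_s`, `duration_s`, `class`,
#'   `amplitude`, `freq`), `morphology` (the jitter multipliers).
#' @export
generateSubject <- function(spec, subjectIndex,
                            subjectId = paste0("S", subjectIndex),
                            classRates = NULL) {
  set.seed(spec$seed + 7919L * as.integer(subjectIndex))
  rates <- if (is.null(classRates)) spec$ratesPerMin else classRates
  sdBg <- spec$rmsUv
  morph <- exp(stats::rnorm(3L, 0, spec$morphologySigma))
  names(morph) <- c("amplitude", "duration", "frequency")

  nSamp <- round(spec$segmentDuration * spec$fs)
  x <- matrix(0, spec$nChannels, nSamp)
  logs <- list()
  for (ch in seq_len(spec$nChannels)) {
    bg <- makeBackground(spec$segmentDuration, spec$fs, spec$alpha,
                         spec$rmsUv)
    counts <- vapply(c("spike", "rons", "ripple"), function(cl) {
      lambda <- rates[[cl]] * spec$segmentDuration / 60
      if (spec$scheduling == "poisson") stats::rpois(1L, lambda)
      else as.integer(round(lambda))
    }, integer(1L))
    nTot <- sum(counts)
    onsets <- .scheduleOnsets(nTot, spec$segmentDuration,
                              spec$minSeparation, headroom = 0.5)
    classes <- sample(rep(names(counts), counts))
    for (k in seq_len(nTot)) {
      cl <- classes[k]
      amp <- NA_real_; f0 <- NA_real_; durS <- NA_real_
      snippet <- NULL
      if (cl %in% c("spike", "rons")) {
        durMs <- stats::runif(1L, spec$spikeDurRangeMs[1],
                              spec$spikeDurRangeMs[2]) * morph["duration"]
        durMs <- min(max(durMs, 20), 70)
        amp <- stats::runif(1L, spec$spikeAmpRange[1],
                            spec$spikeAmpRange[2]) * sdBg * morph["amplitude"]
        snippet <- makeSpike(durMs, amp, spec$fs)
        durS <- durMs / 1000
      }
      if (cl %in% c("ripple", "rons")) {
        f0 <- .clampRippleFreq(.drawRippleFreq(spec$rippleFreqRange) *
                                 morph["frequency"], spec$rippleFreqRange)
        nc <- sample(spec$rippleCycleRange[1]:spec$rippleCycleRange[2], 1L)
        rippleAmp <- stats::runif(1L, spec$rippleAmpRange[1],
                                  spec$rippleAmpRange[2]) * sdBg *
          morph["amplitude"]
        burst <- makeRipple(f0, nc, rippleAmp, spec$fs)
        if (cl == "ripple") {
          snippet <- burst
          amp <- rippleAmp
          durS <- nc / f0
        } else {
          # centre the burst on the spike peak, growing the snippet if
          # the burst overhangs either end
          at <- which.max(snippet) - round(length(burst) / 2)
          lo <- min(1L, at)
          hi <- max(length(snippet), at + length(burst) - 1L)
          buf <- numeric(hi - lo + 1L)
          buf[seq_along(snippet) - lo + 1L] <- snippet
          bi <- (at:(at + length(burst) - 1L)) - lo + 1L
          buf[bi] <- buf[bi] + burst
          snippet <- buf
          durS <- length(snippet) / spec$fs
        }
      }
      # snap the event midpoint into the central part of its time bin
      # (see `binJitter`), then inject
      durSnip <- length(snippet) / spec$fs
      bd <- spec$binDuration
      mid <- onsets[k] + durSnip / 2
      u <- stats::runif(1L, -1, 1) * spec$binJitter
      mid <- (floor(mid / bd) + 0.5 + u / 2) * bd
      onset <- min(max(mid - durSnip / 2, 0),
                   spec$segmentDuration - durSnip - 1 / spec$fs)
      i0 <- round(onset * spec$fs) + 1L
      idx <- i0:(i0 + length(snippet) - 1L)
      bg[idx] <- bg[idx] + snippet
      logs[[length(logs) + 1L]] <- data.frame(
        subject = subjectId, channel = ch, onset_s = onset,
        duration_s = durSnip, class = cl, amplitude = amp, freq = f0,
        stringsAsFactors = FALSE
      )
    }
    if (spec$lineNoiseAmp > 0)
      bg <- bg + spec$lineNoiseAmp *
        sin(2 * pi * 60 * (seq_len(nSamp) - 1L) / spec$fs +
              stats::runif(1L, 0, 2 * pi))
    x[ch, ] <- bg
  }
  log <- if (length(logs)) do.call(rbind, logs) else
    data.frame(subject = character(), channel = integer(),
               onset_s = numeric(), duration_s = numeric(),
               class = character(), amplitude = numeric(),
               freq = numeric())
  list(record = EegRecord(x, fs = spec$fs, subjectId = subjectId),
       log = log, morphology = morph)
}

#' Write a synthetic fixture: EDF file plus CSV injection log
#'
#' @param record an [EegRecord-class].
#' @param log injection-log data.frame from [generateSubject()].
#' @param pathPrefix output path without extension; writes
#'   `<prefix>.edf` and `<prefix>_log.csv`.
#' @return character vector of the two paths, invisibly.
#' @export
writeFixture <- function(record, log, pathPrefix) {
  edf <- paste0(pathPrefix, ".edf")
  csv <- paste0(pathPrefix, "_log.csv")
  writeEDF(record, edf)
  utils::write.csv(log, csv, row.names = FALSE)
  invisible(c(edf, csv))
}

#' Detect events in a record (preprocess -> spectrogram -> detector)
#'
#' The standard analysis chain on one record: preprocessing, 0.25 s
#' eight-band spectrogram, mode-based baseline, relative spectrogram,
#' per-bin candidate labels.
#'
#' @param record an [EegRecord-class].
#' @param detector a [detectorConfig()].
#' @param preprocess a [preprocessConfig()], or `NULL` to skip
#'   filtering (e.g. for already-clean data).
#' @return list: `rel` (a [RelativeSpectrogram-class]), `candidates`
#'   (data.frame from [detectCandidates()]).
#' @export
detectRecord <- function(record, detector = detectorConfig(),
                         preprocess = preprocessConfig()) {
  if (!is.null(preprocess)) record <- preprocessRecord(record, preprocess)
  spec <- bandSpectrogram(record)
  rel <- normalizeSpectrogram(spec, config = detector)
  list(rel = rel,
       candidates = detectCandidates(rel, detector,
                                     subject = subjectId(record)))
}

#' Simulate a multi-subject ground-truth dataset
#'
#' Generates synthetic subjects, runs the threshold detector, verifies
#' candidates against the injection logs (the synthetic stand-in for
#' visual verification) and assembles a balanced ground-truth set with
#' exactly `nPerClass` events per class per subject. The generator
#' schedules `margin` times more injections than needed so that the
#' detector's (>= 90%) recovery still fills every cell; the record
#' duration is derived from those counts.
#'
#' @param nSubjects number of subjects.
#' @param nPerClass ground-truth events per class per subject
#'   (default 200).
#' @param spec a [syntheticSpec()]; its `segmentDuration`,
#'   `ratesPerMin` and `scheduling` are overridden from the counts.
#' @param detector a [detectorConfig()].
#' @param subjectPrefix id prefix (default "S").
#' @param ronsFreeSubjects indices of subjects generated without RonS
#'   events (their rons cell stays empty).
#' @param margin injection surplus factor (default 1.35).
#' @param seed seed for the subsampling step (the generation stream
#'   derives from `spec$seed`).
#' @return list: `gt` (a [GroundTruthSet-class]), `recovery` (named
#'   per-subject injection-recovery fractions), `logs` (per-subject
#'   injection logs).
#' @export
simulateGroundTruth <- function(nSubjects, nPerClass = 200L,
                                spec = syntheticSpec(),
                                detector = detectorConfig(),
                                subjectPrefix = "S",
                                ronsFreeSubjects = integer(),
                                margin = 1.35, seed = spec$seed) {
  perChan <- ceiling(nPerClass * margin / spec$nChannels)
  nTot <- 3L * perChan
  duration <- max(60, ceiling(nTot * (spec$minSeparation + 1.0)))
  spec$segmentDuration <- duration
  spec$ratesPerMin <- c(spike = 1, rons = 1, ripple = 1) *
    perChan / duration * 60
  spec$scheduling <- "exact"

  perSubject <- list(); recovery <- c(); logs <- list()
  for (k in seq_len(nSubjects)) {
    sid <- paste0(subjectPrefix, k)
    rates <- spec$ratesPerMin
    if (k %in% ronsFreeSubjects) rates["rons"] <- 0
    sub <- generateSubject(spec, k, subjectId = sid, classRates = rates)
    det <- detectRecord(sub$record, detector)
    ver <- verifyCandidates(det$candidates, sub$log,
                            binDuration = binDuration(det$rel))
    labelled <- rbind(ver$events, ver$baseline)
    perSubject[[sid]] <- list(rel = det$rel, candidates = labelled)
    recovery[sid] <- ver$recovery
    logs[[sid]] <- sub$log
  }
  gt <- assembleGroundTruth(perSubject, nPerClass = nPerClass, seed = seed)
  list(gt = gt, recovery = recovery, logs = logs)
}
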
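# Shared fixture builders. Everything is generated in code; no data
# files.

fsDefault <- 500

# single-channel record from a numeric vector
chRecord <- function(x, fs = fsDefault) EegRecord(matrix(x, nrow = 1), fs)

# a RelativeSpectrogram built directly from a ratio array
relFromArray <- function(rel, binDuration = 0.25) {
  d <- dim(rel)
  new("RelativeSpectrogram", relPower = rel, binDuration = binDuration,
      bandSet = defaultBandSet(),
      baseline = matrix(1, d[1], d[2]), t0 = 0,
      channelLabels = paste0("ch", seq_len(d[1])))
}

# inject one snippet into fresh 1/f background and run the detector;
# returns the relative powers of the 3 bins around the event midpoint
injectAndDetect <- function(snippet, onset = 30.06, durationS = 90,
                            seed = 1, fs = fsDefault) {
  set.seed(seed)
  bg <- makeBackground(durationS, fs, 1, 20)
  i0 <- round(onset * fs) + 1
  bg[i0:(i0 + length(snippet) - 1)] <- bg[i0:(i0 + length(snippet) - 1)] +
    snippet
  det <- detectRecord(chRecord(bg, fs))
  midBin <- floor((onset + length(snippet) / fs / 2) / 0.25) + 1
  list(det = det,
       window = det$candidates[abs(det$candidates$bin - midBin) <= 1, ])
}

# small balanced ground-truth set with well-separated class signatures
toyGroundTruth <- function(nPerClass = 60, subjects = "S1", seed = 1,
                           noise = 0.2) {
  set.seed(seed)
  cls <- eventClasses()
  n <- nPerClass * length(cls) * length(subjects)
  feats <- array(abs(stats::rnorm(8 * 3 * n, 1, noise)), c(8, 3, n))
  labs <- character(n); subj <- character(n)
  i <- 0
  for (sj in subjects) for (cl in cls) for (k in seq_len(nPerClass)) {
    i <- i + 1
    labs[i] <- cl; subj[i] <- sj
    if (cl %in% c("spike", "rons")) {
      feats[3, 2, i] <- feats[3, 2, i] + 6   # beta
      feats[4, 2, i] <- feats[4, 2, i] + 6   # gamma1
    }
    if (cl %in% c("ripple", "rons")) feats[6, 2, i] <- feats[6, 2, i] + 9
  }
  info <- data.frame(subject = subj, channel = 1L, bin = seq_len(n),
                     time_s = (seq_len(n) - 1) * 0.25,
                     label = factor(labs, levels = cls),
                     stringsAsFactors = FALSE)
  new("GroundTruthSet", features = feats, info = info)
}

# brute-force per-bin classification, the oracle for detectCandidates
bruteForceLabels <- function(rel, config = detectorConfig()) {
  rp <- relPower(rel)
  d <- dim(rp)
  out <- matrix("", d[1], d[3])
  for (ch in seq_len(d[1]))
    for (b in seq_len(d[3]))
      out[ch, b] <- classifyBin(rp[ch, , b], config)
  out
}
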
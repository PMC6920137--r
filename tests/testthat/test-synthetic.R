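test_that("background noise has the requested spectral slope and RMS", {
  x <- makeBackground(120, 500, alpha = 1, rms = 20, seed = 3)
  expect_equal(sqrt(mean(x^2)), 20, tolerance = 1e-9)
  # periodogram slope over 4-200 Hz
  n <- length(x)
  pg <- Mod(fft(x))^2 / n
  f <- (seq_len(n) - 1) * 500 / n
  sel <- f >= 4 & f <= 200
  # average the periodogram in log-spaced bands for a stable fit
  lf <- log10(f[sel]); lp <- log10(pg[sel])
  bins <- cut(lf, 24)
  fit <- stats::lm(tapply(lp, bins, mean) ~ tapply(lf, bins, mean))
  expect_lt(abs(coef(fit)[2] + 1), 0.2)
  # doubling RMS quadruples band power
  x2 <- makeBackground(60, 500, 1, 10, seed = 5)
  x4 <- makeBackground(60, 500, 1, 20, seed = 5)
  p2 <- bandPower(bandSpectrogram(chRecord(x2)))
  p4 <- bandPower(bandSpectrogram(chRecord(x4)))
  expect_equal(p4, 4 * p2, tolerance = 1e-9)
  # seeded reproducibility
  expect_identical(makeBackground(10, 500, 1, 20, seed = 7),
                   makeBackground(10, 500, 1, 20, seed = 7))
  expect_error(makeBackground(5, 500, 1, 20), "duration")
  expect_error(makeBackground(20, 500, 3, 20), "alpha")
})

test_that("spike snippets are biphasic, zero-mean and duration-checked", {
  s <- makeSpike(40, 150, 500)
  expect_equal(max(abs(s)), 150)
  expect_gt(max(s), 0)
  expect_lt(min(s), 0)                           # opposite deflection
  expect_equal(sum(s), 0, tolerance = 1e-9 * sum(abs(s)))
  expect_equal(max(abs(makeSpike(40, 0, 500))), 0)
  expect_error(makeSpike(10, 1, 500), "spec error")
  expect_error(makeSpike(80, 1, 500), "spec error")
})

test_that("ripple snippets respect band membership and cycle count", {
  r <- makeRipple(150, 6, 80, 500)
  expect_equal(length(r), round(6 / 150 * 500))
  expect_equal(max(abs(r)), 80)
  expect_error(makeRipple(150, 3, 80, 500), "3 oscillation")
  expect_error(makeRipple(180, 6, 80, 500), "passband")   # inter-band gap
  expect_error(makeRipple(60, 6, 80, 500), "passband")
})

test_that("injected spikes satisfy the spike criterion but not the ripple
           criterion (no false RonS)", {
  hits <- sapply(1:30, function(s) {
    set.seed(100 + s)
    sn <- makeSpike(runif(1, 20, 70), runif(1, 8, 10) * 20, 500)
    w <- injectAndDetect(sn, seed = 200 + s, durationS = 60,
                         onset = 30.08)$window
    c(spike = any(w$label == "spike"),
      noRons = !any(w$label == "rons"))
  })
  expect_gte(mean(hits["spike", ]), 0.95)
  expect_gte(mean(hits["noRons", ]), 0.95)
})

test_that("injected ripples satisfy the ripple criterion only", {
  hits <- sapply(1:30, function(s) {
    set.seed(300 + s)
    f0 <- c(150, 190, 220)[sample(3, 1)]
    sn <- makeRipple(f0, sample(4:8, 1), runif(1, 4, 6) * 20, 500)
    w <- injectAndDetect(sn, seed = 400 + s, durationS = 60,
                         onset = 30.09)$window
    c(ripple = any(w$label == "ripple"),
      noSpike = !any(w$label %in% c("spike", "rons")))
  })
  expect_gte(mean(hits["ripple", ]), 0.95)
  expect_gte(mean(hits["noSpike", ]), 0.95)
})

test_that("subject generation schedules separated, reproducible events", {
  spec <- syntheticSpec(nChannels = 2, segmentDuration = 120,
                        ratesPerMin = c(spike = 2, rons = 2, ripple = 2),
                        scheduling = "exact", seed = 31)
  sub <- generateSubject(spec, 1)
  log <- sub$log
  expect_equal(nrow(log), 2 * 3 * 4)             # 2 ch x 3 classes x 4/ch
  expect_equal(dim(samples(sub$record)), c(2, 120 * 500))
  for (ch in 1:2) {
    ons <- sort(log$onset_s[log$channel == ch])
    expect_true(all(diff(ons) >= 1))
  }
  # reproducible from (spec, index); different across indices
  sub2 <- generateSubject(spec, 1)
  expect_identical(samples(sub$record), samples(sub2$record))
  subB <- generateSubject(spec, 2)
  expect_false(identical(sub$morphology, subB$morphology))
  # rons-free subjects
  noRons <- generateSubject(spec, 1,
                            classRates = c(spike = 2, rons = 0, ripple = 2))
  expect_equal(sum(noRons$log$class == "rons"), 0)
  # impossible rates raise a scheduling error
  dense <- syntheticSpec(nChannels = 1, segmentDuration = 60,
                         ratesPerMin = c(spike = 20, rons = 20,
                                         ripple = 20),
                         scheduling = "exact", seed = 1)
  expect_error(generateSubject(dense, 1), "scheduling error")
})

test_that("the detector recovers injected events by class (the
           generator-detector contract)", {
  recov <- sapply(1:10, function(seed) {
    spec <- syntheticSpec(nChannels = 2, segmentDuration = 100,
                          ratesPerMin = c(spike = 2, rons = 2, ripple = 2),
                          scheduling = "exact", seed = seed)
    sub <- generateSubject(spec, 1)
    det <- detectRecord(sub$record)
    verifyCandidates(det$candidates, sub$log)$recovery
  })
  expect_gte(mean(recov), 0.9)
  expect_gte(min(recov), 0.75)
})

test_that("60 Hz line interference leaves all band powers untouched", {
  spec0 <- syntheticSpec(nChannels = 1, segmentDuration = 60,
                         ratesPerMin = c(spike = 1, rons = 1, ripple = 1),
                         scheduling = "exact", seed = 77)
  spec1 <- spec0
  spec1$lineNoiseAmp <- 30
  p0 <- bandPower(bandSpectrogram(generateSubject(spec0, 1)$record))
  p1 <- bandPower(bandSpectrogram(generateSubject(spec1, 1)$record))
  expect_equal(mean(p1[1, 5, ]) / mean(p0[1, 5, ]), 1, tolerance = 0.01)
  for (b in 1:8)
    expect_equal(mean(p1[1, b, ]), mean(p0[1, b, ]), tolerance = 0.01)
})

test_that("fixtures round-trip: EDF + injection-log CSV", {
  spec <- syntheticSpec(nChannels = 2, segmentDuration = 30,
                        ratesPerMin = c(spike = 2, rons = 0, ripple = 2),
                        scheduling = "exact", seed = 5)
  spec$segmentDuration <- 30   # short fixture
  sub <- generateSubject(spec, 1)
  prefix <- tempfile()
  paths <- writeFixture(sub$record, sub$log, prefix)
  back <- readEDF(paste0(prefix, ".edf"))
  expect_equal(nChannels(back), 2)
  expect_equal(samplingRate(back), 500)
  lsb <- max(abs(samples(sub$record))) * 1.0001 / 32767
  expect_lt(max(abs(samples(back) - samples(sub$record))), lsb + 1e-9)
  logBack <- read.csv(paste0(prefix, "_log.csv"))
  expect_equal(nrow(logBack), nrow(sub$log))
})

test_that("simulated ground truth fills every class cell, with optional
           rons-free subjects", {
  sim <- suppressMessages(simulateGroundTruth(
    2, nPerClass = 30, spec = syntheticSpec(nChannels = 2, seed = 19),
    ronsFreeSubjects = 2, seed = 19))
  counts <- eventCounts(sim$gt)
  expect_true(all(counts["S1", ] == 30))
  expect_equal(unname(counts["S2", "rons"]), 0)
  expect_true(all(counts["S2", c("spike", "ripple", "baseline")] == 30))
  expect_gte(sim$recovery[["S1"]], 0.9)
})
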
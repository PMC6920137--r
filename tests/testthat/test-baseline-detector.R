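test_that("baseline equals the constant for a constant series", {
  expect_equal(estimateBaseline(rep(3.7, 500)), 3.7)
})

test_that("baseline tracks the log-normal mode scale where the mean cannot", {
  errs <- sapply(1:20, function(s) {
    set.seed(s)
    estimateBaseline(exp(rnorm(10000, log(10), 0.5))) / 10 - 1
  })
  expect_lt(max(abs(errs)), 0.03)
  # the plain mean overestimates by about exp(sigma^2 / 2)
  set.seed(1)
  expect_gt(mean(exp(rnorm(10000, log(10), 0.5))) / 10, 1.08)
})

test_that("baseline is robust to a 5 percent high-power contamination", {
  shift <- sapply(1:20, function(s) {
    set.seed(s)
    x <- exp(rnorm(10000, log(10), 0.5))
    clean <- estimateBaseline(x)
    i <- sample(10000, 500)
    x[i] <- x[i] * 50
    c(estimateBaseline(x) / clean - 1, mean(x) / 10 - 1)
  })
  expect_lt(max(abs(shift[1, ])), 0.02)   # mode region barely moves
  expect_gt(min(shift[2, ]), 1)           # the mean more than doubles
})

test_that("baseline estimate is scale-equivariant and validates input", {
  set.seed(5)
  x <- exp(rnorm(2000, 0, 0.4))
  expect_equal(estimateBaseline(1e6 * x), 1e6 * estimateBaseline(x))
  expect_error(estimateBaseline(rep(0, 500)), "zero")
  expect_warning(estimateBaseline(exp(rnorm(50))), "100")
  expect_message(estimateBaseline(c(rep(0, 200), x)), "zero")
  # the histogram-peak variant stays within a few percent too
  cfg <- detectorConfig(histogramBins = 40L)
  expect_equal(estimateBaseline(x, cfg), estimateBaseline(x),
               tolerance = 0.2)
})

test_that("log-normality diagnostic behaves as expected", {
  pOk <- sapply(1:20, function(s) {
    set.seed(s)
    checkLogNormality(exp(rnorm(10000, 1, 0.5)))$p.value
  })
  expect_gte(mean(pOk > 0.05), 0.9)
  pBad <- sapply(1:20, function(s) {
    set.seed(s)
    checkLogNormality(runif(10000))$p.value
  })
  expect_gte(mean(pBad < 0.01), 0.9)
  const <- suppressWarnings(checkLogNormality(rep(2, 500)))
  expect_true(is.na(const$p.value))
})

test_that("normalisation divides by baseline and is scale-invariant", {
  set.seed(7)
  pw <- array(abs(rnorm(2 * 8 * 120, 5, 1)), c(2, 8, 120))
  spec <- new("BandSpectrogram", power = pw, binDuration = 0.25,
              bandSet = defaultBandSet(), t0 = 0,
              channelLabels = c("a", "b"))
  base <- matrix(2, 2, 8)
  rel <- normalizeSpectrogram(spec, base)
  expect_equal(relPower(rel), pw / 2)
  # equal spec and baseline -> all ones
  one <- normalizeSpectrogram(spec, matrix(5, 2, 8))
  spec5 <- new("BandSpectrogram", power = array(5, c(2, 8, 120)),
               binDuration = 0.25, bandSet = defaultBandSet(), t0 = 0,
               channelLabels = c("a", "b"))
  expect_true(all(relPower(normalizeSpectrogram(spec5,
                                                matrix(5, 2, 8))) == 1))
  # joint rescaling leaves ratios unchanged
  spec10 <- new("BandSpectrogram", power = pw * 10, binDuration = 0.25,
                bandSet = defaultBandSet(), t0 = 0,
                channelLabels = c("a", "b"))
  expect_equal(relPower(normalizeSpectrogram(spec10, base * 10)),
               relPower(rel))
  expect_error(normalizeSpectrogram(spec, matrix(1, 3, 8)), "channels")
})

test_that("per-bin classification follows the threshold rules", {
  expect_equal(classifyBin(c(1, 1, 5, 5, 5, 1, 1, 1)), "spike")
  expect_equal(classifyBin(c(1, 1, 1, 1, 1, 8, 1, 1)), "ripple")
  expect_equal(classifyBin(c(1, 1, 5, 5, 5, 9, 1, 1)), "rons")
  expect_equal(classifyBin(rep(1, 8)), "baseline")
  # exactly at threshold counts
  expect_equal(classifyBin(c(1, 1, 4, 4, 1, 1, 1, 1)), "spike")
  expect_equal(classifyBin(c(1, 1, 1, 1, 1, 1, 7, 1)), "ripple")
  # spike needs beta AND a gamma band
  expect_equal(classifyBin(c(1, 1, 5, 1, 1, 1, 1, 1)), "baseline")
  expect_equal(classifyBin(c(1, 1, 1, 5, 5, 1, 1, 1)), "baseline")
  # strict gamma mode requires both gamma sub-bands
  strict <- detectorConfig(gammaMode = "both")
  expect_equal(classifyBin(c(1, 1, 5, 5, 1, 1, 1, 1), strict), "baseline")
  expect_equal(classifyBin(c(1, 1, 5, 5, 5, 1, 1, 1), strict), "spike")
})

test_that("classification is monotone in the ratios", {
  set.seed(31)
  for (k in 1:200) {
    r <- runif(8, 0.2, 10)
    lab <- classifyBin(r)
    # raising a ripple sub-band past 7 on a spike bin gives rons
    if (lab == "spike") {
      r2 <- r; r2[6] <- 8
      expect_equal(classifyBin(r2), "rons")
    }
    # raising any single ratio never turns rons into spike or ripple
    if (lab == "rons") {
      i <- sample(8, 1)
      r2 <- r; r2[i] <- r2[i] * 2
      expect_equal(classifyBin(r2), "rons")
    }
  }
})

test_that("detector output partitions bins and matches brute force", {
  set.seed(33)
  rel <- relFromArray(array(exp(rnorm(3 * 8 * 50, 0, 1.2)), c(3, 8, 50)))
  cand <- detectCandidates(rel)
  expect_equal(nrow(cand), 3 * 50)
  expect_equal(sum(table(cand$label)), 3 * 50)
  oracle <- bruteForceLabels(rel)
  for (i in seq_len(nrow(cand)))
    expect_equal(as.character(cand$label[i]),
                 oracle[cand$channel[i], cand$bin[i]])
  # targeted placements come out at the right (channel, bin)
  rel2arr <- array(1, c(2, 8, 20))
  rel2arr[1, 3:5, 4] <- 5                     # spike at channel 1, bin 4
  rel2arr[2, 6, 11] <- 8                      # ripple at channel 2, bin 11
  cand2 <- detectCandidates(relFromArray(rel2arr))
  nb <- cand2[cand2$label != "baseline", ]
  expect_equal(nrow(nb), 2)
  expect_equal(nb$channel[nb$label == "spike"], 1)
  expect_equal(nb$bin[nb$label == "spike"], 4)
  expect_equal(nb$bin[nb$label == "ripple"], 11)
})

test_that("adjacent same-label bins merge into single intervals", {
  arr <- array(1, c(1, 8, 20))
  arr[1, 3:5, 6:8] <- 5
  m <- mergeCandidates(detectCandidates(relFromArray(arr)))
  expect_equal(nrow(m), 1)
  expect_equal(m$nBins, 3)
  expect_equal(m$start_s, 1.25)
  expect_equal(m$end_s, 2.0)
})
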
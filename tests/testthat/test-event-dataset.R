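test_that("feature extraction returns the 3-bin context with edge rules", {
  arr <- array(1, c(2, 8, 10))
  arr[1, 6, 5] <- 8
  rel <- relFromArray(arr)
  f <- extractFeature(rel, channel = 1, bin = 4)
  expect_equal(dim(f), c(8, 3))
  expect_equal(f[6, 3], 8)                      # next bin carries the ripple
  f5 <- extractFeature(rel, 1, 5)
  expect_equal(f5[6, 2], 8)
  expect_equal(unname(f5[, 1]), rep(1, 8))
  # all-ones input -> all-ones features
  expect_true(all(extractFeature(relFromArray(array(1, c(1, 8, 6))),
                                 1, 3) == 1))
  # edge replication at both ends
  fFirst <- extractFeature(rel, 1, 1)
  expect_equal(fFirst[, 1], fFirst[, 2])
  fLast <- extractFeature(rel, 1, 10)
  expect_equal(fLast[, 3], fLast[, 2])
  # batch version agrees with the scalar one
  cand <- data.frame(channel = c(1, 1, 2), bin = c(1, 5, 10))
  fb <- extractFeatures(rel, cand)
  expect_equal(fb[, , 2], unname(extractFeature(rel, 1, 5)))
  expect_equal(fb[, , 1], unname(extractFeature(rel, 1, 1)))
})

test_that("ground-truth assembly subsamples per class deterministically", {
  arr <- array(1, c(1, 8, 3000))
  spikeBins <- seq(2, 2400, by = 2)             # 1200 spike candidates
  arr[1, 3:5, spikeBins] <- 6
  rel <- relFromArray(arr)
  cand <- detectCandidates(rel, subject = "P1")
  per <- list(P1 = list(rel = rel, candidates = cand))
  gt <- suppressMessages(assembleGroundTruth(per, nPerClass = 1000,
                                             seed = 42))
  info <- eventInfo(gt)
  expect_equal(sum(info$label == "spike"), 1000)
  expect_equal(anyDuplicated(info[, c("subject", "channel", "bin")]), 0)
  # a missing class yields an empty cell, not an error
  expect_equal(sum(info$label == "rons"), 0)
  # determinism
  gt2 <- suppressMessages(assembleGroundTruth(per, nPerClass = 1000,
                                              seed = 42))
  expect_identical(eventInfo(gt2), info)
  gt3 <- suppressMessages(assembleGroundTruth(per, nPerClass = 1000,
                                              seed = 43))
  expect_false(identical(eventInfo(gt3), info))
})

test_that("splits are balanced, disjoint and reproducible", {
  gt <- toyGroundTruth(nPerClass = 100, subjects = c("A", "B"))
  sp <- makeSplits(gt, nTrain = 30, nTest = 50, nRandomizations = 10,
                   seed = 9)
  info <- eventInfo(gt)
  expect_length(sp, 10)
  for (s in sp) {
    expect_length(intersect(s$train, s$test), 0)
    tab <- table(info$subject[s$train], info$label[s$train])
    expect_true(all(tab == 30))
    tabT <- table(info$subject[s$test], info$label[s$test])
    expect_true(all(tabT == 50))
    # 100 - 30 - 50 = 20 unused per cell
    expect_equal(nrow(info) - length(s$train) - length(s$test),
                 20 * 8)
  }
  expect_identical(makeSplits(gt, 30, 50, 10, seed = 9), sp)
  expect_false(identical(makeSplits(gt, 30, 50, 10, seed = 10)[[1]],
                         sp[[1]]))
  expect_error(makeSplits(gt, 60, 50), "split error")
})

test_that("ground-truth sets round-trip through CSV", {
  gt <- toyGroundTruth(nPerClass = 10)
  path <- tempfile(fileext = ".csv")
  writeGroundTruthCsv(gt, path)
  back <- readGroundTruthCsv(path)
  expect_equal(eventFeatures(back), eventFeatures(gt))
  expect_equal(eventInfo(back)$label, eventInfo(gt)$label)
})

test_that("candidate verification matches injections and guards baseline", {
  arr <- array(1, c(1, 8, 120))
  arr[1, 3:5, 21] <- 6                          # spike at bin 21 (5.0-5.25 s)
  arr[1, 6, 61] <- 9                            # ripple at bin 61 (15 s)
  rel <- relFromArray(arr)
  cand <- detectCandidates(rel)
  log <- data.frame(channel = 1, onset_s = c(5.05, 15.02),
                    duration_s = c(0.05, 0.04),
                    class = c("spike", "ripple"))
  ver <- verifyCandidates(cand, log)
  expect_equal(ver$recovery, 1)
  expect_setequal(ver$events$bin, c(21, 61))
  # no baseline bin within 1 s of an injection
  expect_true(all(abs(ver$baseline$time_s - 5.05) > 0.95 |
                    abs(ver$baseline$time_s - 15.02) > 0.95))
  # a mislabelled injection is not matched
  log2 <- data.frame(channel = 1, onset_s = 5.05, duration_s = 0.05,
                     class = "ripple")
  expect_equal(verifyCandidates(cand, log2)$recovery, 0)
})
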
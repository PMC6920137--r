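test_that("confusion counts and metric formulas are exact", {
  cls <- eventClasses()
  truth <- rep(cls, each = 100)
  perfect <- computeMetrics(confusionCounts(truth, truth))
  expect_equal(unname(diag(confusion(perfect))), rep(100, 4))
  expect_equal(totalAccuracy(perfect), 100)
  expect_equal(perClassMetrics(perfect)$sens, rep(100, 4))
  expect_equal(perClassMetrics(perfect)$spec, rep(100, 4))
  # all predicted baseline: only that column is nonzero
  allBase <- confusionCounts(truth, rep("baseline", 400))
  expect_true(all(allBase[, 1:3] == 0))
  expect_equal(sum(allBase[, 4]), 400)
  # empty input gives an all-zero matrix, which computeMetrics rejects
  empty <- confusionCounts(character(), character())
  expect_true(all(empty == 0))
  expect_error(computeMetrics(empty), "empty-report")
  expect_error(confusionCounts(c("spike"), character()), "length")
  # formula spot checks
  cm <- matrix(0, 4, 4)
  cm[1, 1] <- 450; cm[1, 4] <- 50; cm[2, 2] <- 500
  cm[3, 3] <- 475; cm[4, 3] <- 25; cm[4, 4] <- 475
  r <- computeMetrics(cm)
  pc <- perClassMetrics(r)
  expect_equal(pc$sens[pc$class == "spike"], 90)
  expect_equal(pc$spec[pc$class == "ripple"],
               100 * (1 - 25 / 1500), tolerance = 1e-12)
})

test_that("accuracy equals the positive-weighted mean of sensitivities", {
  set.seed(41)
  for (k in 1:50) {
    cm <- matrix(rpois(16, 40), 4, 4)
    r <- computeMetrics(cm)
    pc <- perClassMetrics(r)
    expect_equal(totalAccuracy(r),
                 sum(pc$P * pc$sens) / sum(pc$P), tolerance = 1e-12)
    # metrics invariant to scaling all counts
    r3 <- computeMetrics(cm * 3)
    expect_equal(perClassMetrics(r3)$sens, pc$sens)
    expect_equal(perClassMetrics(r3)$spec, pc$spec)
  }
})

test_that("a class with no positive cases reports undefined sensitivity", {
  cm <- diag(c(100, 0, 100, 100))
  pc <- perClassMetrics(computeMetrics(cm))
  expect_true(is.na(pc$sens[pc$class == "rons"]))
  expect_false(anyNA(pc$spec))
})

test_that("uniform-random prediction gives ~25% accuracy, ~75% specificity", {
  set.seed(43)
  truth <- rep(eventClasses(), each = 2500)
  pred <- sample(eventClasses(), 10000, replace = TRUE)
  r <- computeMetrics(confusionCounts(truth, pred))
  expect_equal(totalAccuracy(r), 25, tolerance = 0.1)   # relative
  expect_equal(perClassMetrics(r)$spec, rep(75, 4), tolerance = 0.03)
})

test_that("aggregation reports mean and sample SD with NA propagation", {
  cm <- diag(c(90, 90, 90, 90)); cm[1, 2] <- 10
  r <- computeMetrics(cm)
  agg10 <- aggregateReports(rep(list(r), 10))
  expect_true(all(agg10$sd == 0))
  expect_equal(agg10$mean[agg10$metric == "accuracy"], totalAccuracy(r))
  # two reports with accuracies 90 and 92
  cmA <- diag(c(90, 90, 90, 90)); cmA[1, 2] <- 40   # acc = 360/400 = 90
  cmB <- diag(c(92, 90, 92, 94)); cmB[1, 2] <- 32   # acc = 368/400 = 92
  agg2 <- aggregateReports(list(computeMetrics(cmA), computeMetrics(cmB)))
  expect_equal(agg2$mean[agg2$metric == "accuracy"], 91)
  expect_equal(agg2$sd[agg2$metric == "accuracy"], sqrt(2))
  # single report: mean = report, sd undefined
  agg1 <- aggregateReports(list(r))
  expect_true(all(is.na(agg1$sd)))
  # NA cells stay NA
  aggNA <- aggregateReports(list(computeMetrics(diag(c(10, 0, 10, 10)))))
  expect_true(is.na(aggNA$mean[aggNA$metric == "sens_rons"]))
})
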
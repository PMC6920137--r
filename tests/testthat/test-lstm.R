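test_that("parameter count matches the closed form for LSTM layers", {
  # one bidirectional layer: 2 directions x 4 gates x (H*(D+H) + H),
  # plus a fully connected 4 x 2H + 4
  for (H in c(20, 50, 200)) {
    m <- buildLstm(lstmConfig(hiddenUnits = H))
    expect_equal(nParams(m), 2 * 4 * (H * (8 + H) + H) + 4 * 2 * H + 4)
  }
  # unidirectional single layer
  m1 <- buildLstm(lstmConfig(hiddenUnits = 30, bidirectional = FALSE))
  expect_equal(nParams(m1), 4 * (30 * 38 + 30) + 4 * 30 + 4)
  # two stacked bidirectional layers: layer 2 consumes 2H features
  H <- 10
  m2 <- buildLstm(lstmConfig(hiddenUnits = H, layers = 2))
  expect_equal(nParams(m2),
               2 * 4 * (H * (8 + H) + H) +
                 2 * 4 * (H * (2 * H + H) + H) + 4 * 2 * H + 4)
  expect_true(all(c("L2f_Wx", "L2b_Wx") %in% names(m2@params)))
})

test_that("softmax outputs are proper probabilities with stable argmax", {
  m <- buildLstm(lstmConfig(hiddenUnits = 8, seed = 2))
  set.seed(3)
  X <- array(abs(rnorm(8 * 3 * 17)), c(8, 3, 17))
  p <- predict(m, X)
  expect_equal(colSums(p$prob), rep(1, 17), tolerance = 1e-12)
  expect_true(all(p$prob >= 0))
  # logit shift invariance
  m2 <- m
  m2@params$FC_b <- m@params$FC_b + 13.7
  expect_equal(predict(m2, X)$prob, p$prob, tolerance = 1e-9)
  # exact tie breaks toward the first class in order
  mTie <- m
  mTie@params$FC_W[] <- 0
  mTie@params$FC_b <- rep(0, 4)
  expect_equal(as.character(predict(mTie, X)$label),
               rep("spike", 17))
  # batch prediction equals event-by-event prediction
  one <- sapply(1:17, function(i)
    as.character(predict(m, X[, , i])$label))
  expect_equal(as.character(p$label), one)
  expect_error(predict(m, array(1, c(5, 3, 2))), "8 x 3")
})

test_that("analytic gradients match numerical differentiation", {
  ns <- asNamespace("hfoLSTM")
  for (cfg in list(lstmConfig(hiddenUnits = 3, seed = 7),
                   lstmConfig(hiddenUnits = 3, layers = 2,
                              bidirectional = FALSE, seed = 8))) {
    m <- buildLstm(cfg, inputDim = 2)
    set.seed(1)
    X <- array(rnorm(2 * 3 * 5), c(2, 3, 5))
    Y <- ns$.oneHot(sample(eventClasses(), 5, replace = TRUE),
                    eventClasses())
    loss <- function(params) {
      fw <- ns$.modelForward(params, X, m@config, training = FALSE)
      -mean(log(colSums(fw$probs * Y)))
    }
    fw <- ns$.modelForward(m@params, X, m@config, training = FALSE)
    gr <- ns$.modelBackward(m@params, fw, Y, m@config)
    set.seed(2)
    for (nm in names(m@params)) {
      for (j in sample(seq_along(m@params[[nm]]),
                       min(4, length(m@params[[nm]])))) {
        p <- m@params
        e <- 1e-5
        p[[nm]][j] <- m@params[[nm]][j] + e
        up <- loss(p)
        p[[nm]][j] <- m@params[[nm]][j] - e
        dn <- loss(p)
        num <- (up - dn) / (2 * e)
        expect_equal(gr[[nm]][j], num, tolerance = 1e-4)
      }
    }
  }
})

test_that("training is deterministic, seed-governed and validates input", {
  gt <- toyGroundTruth(nPerClass = 30)
  m0 <- buildLstm(lstmConfig(hiddenUnits = 6, nIterations = 40, seed = 5))
  mA <- trainLstm(m0, gt)
  mB <- trainLstm(m0, gt)
  X <- eventFeatures(gt)
  expect_identical(predict(mA, X)$prob, predict(mB, X)$prob)
  mC <- trainLstm(m0, gt, seed = 6)
  expect_false(identical(predict(mA, X)$prob, predict(mC, X)$prob))
  # zero iterations returns the model unchanged
  mZ <- trainLstm(m0, gt, nIterations = 0)
  expect_identical(mZ@params, m0@params)
  # a single-class training set is degenerate
  one <- array(1, c(8, 3, 10))
  expect_error(trainLstm(m0, one, rep("spike", 10)), "degenerate")
})

test_that("the network learns a separable toy problem completely", {
  set.seed(2)
  n <- 400
  X <- array(abs(rnorm(8 * 3 * n, 0, 0.3)), c(8, 3, n))
  lab <- rep(eventClasses(), each = n / 4)
  for (i in seq_len(n)) X[match(lab[i], eventClasses()), 2, i] <- 10
  m <- buildLstm(lstmConfig(hiddenUnits = 20, nIterations = 200, seed = 3))
  m <- trainLstm(m, X, lab)
  expect_equal(mean(as.character(predict(m, X)$label) == lab), 1)
  # loss decreases over training
  h <- m@history
  expect_lt(mean(tail(h, 20)), 0.2 * mean(head(h, 20)))
  expect_true(m@trained)
  expect_equal(m@manifest$nIterations, 200)
})

test_that("accuracy is non-decreasing in training iterations on the toy set", {
  set.seed(12)
  n <- 240
  X <- array(abs(rnorm(8 * 3 * n, 0, 1)), c(8, 3, n))
  lab <- rep(eventClasses(), each = n / 4)
  for (i in seq_len(n)) X[match(lab[i], eventClasses()), 2, i] <-
    X[match(lab[i], eventClasses()), 2, i] + 3
  acc <- sapply(c(50, 200, 1000), function(ni) {
    m <- trainLstm(buildLstm(lstmConfig(hiddenUnits = 10,
                                        nIterations = ni, seed = 4)), X, lab)
    mean(as.character(predict(m, X)$label) == lab)
  })
  expect_true(all(diff(acc) >= -0.02))
  expect_gt(acc[3], 0.9)
})

test_that("training on label-independent features yields chance-level
           test accuracy", {
  accs <- sapply(1:5, function(s) {
    set.seed(s)
    n <- 320
    X <- array(abs(rnorm(8 * 3 * n)), c(8, 3, n))   # no class structure
    lab <- rep(eventClasses(), length.out = n)
    trainIdx <- 1:240; testIdx <- 241:320
    m <- buildLstm(lstmConfig(hiddenUnits = 8, nIterations = 150,
                              seed = s))
    m <- trainLstm(m, X[, , trainIdx], sample(lab[trainIdx]), seed = s)
    mean(as.character(predict(m, X[, , testIdx])$label) == lab[testIdx])
  })
  expect_lt(abs(mean(accs) - 0.25), 0.05)
})

test_that("models round-trip through checkpoints", {
  gt <- toyGroundTruth(nPerClass = 20)
  m <- trainLstm(buildLstm(lstmConfig(hiddenUnits = 5, nIterations = 20,
                                      seed = 1)), gt)
  path <- tempfile(fileext = ".rds")
  saveLstm(m, path)
  back <- loadLstm(path)
  X <- eventFeatures(gt)
  expect_identical(predict(back, X)$prob, predict(m, X)$prob)
  expect_identical(back@manifest$dataHash, m@manifest$dataHash)
})
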
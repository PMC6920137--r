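# The multi-subject global experiment (7 training-site + 2
# held-out-site synthetic subjects, 200 events/class/subject) is used
# by several acceptance checks; build it once per test run.

.globalCache <- new.env(parent = emptyenv())

globalDataset <- function(seed = 42L) {
  key <- paste0("s", seed)
  if (is.null(.globalCache[[key]])) {
    specA <- syntheticSpec(seed = seed)
    simA <- suppressMessages(
      simulateGroundTruth(7, nPerClass = 200, spec = specA, seed = seed))
    specB <- syntheticSpec(seed = seed + 5000L)
    simB <- suppressMessages(
      simulateGroundTruth(2, nPerClass = 200, spec = specB,
                          subjectPrefix = "B", seed = seed + 5000L))
    .globalCache[[key]] <- list(train = simA, holdout = simB)
  }
  .globalCache[[key]]
}

globalExperiment <- function(seed = 42L, hiddenUnits = 50L,
                             nIterations = 500L) {
  ds <- globalDataset(seed)
  runExperiment("cross_site", ds$train$gt, nTrain = 100L, nTest = 100L,
                nRandomizations = 3L,
                config = lstmConfig(hiddenUnits = hiddenUnits,
                                    nIterations = nIterations,
                                    seed = seed),
                gtHoldout = ds$holdout$gt, seed = seed)
}
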
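# Pipeline orchestration: YAML config, run manifests, and the
# simulate / detect / experiment entry points used by the command-line
# front end (inst/cli/hfolstm.R).

#' Read a pipeline configuration file
#'
#' A single YAML file with optional sections `preprocess`, `detector`,
#' `lstm`, `synthetic`, `excludeChannels` and `seed`; omitted fields
#' take the package defaults. Returns fully resolved config objects.
#'
#' @param path YAML file path, or `NULL` for all defaults.
#' @return list: `preprocess`, `detector`, `lstm`, `synthetic`,
#'   `excludeChannels`, `seed`.
#' @export
readPipelineConfig <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  mk <- function(fn, section) {
    args <- raw[[section]]
    if (is.null(args)) args <- list()
    do.call(fn, args)
  }
  list(
    preprocess = mk(preprocessConfig, "preprocess"),
    detector = mk(detectorConfig, "detector"),
    lstm = mk(lstmConfig, "lstm"),
    synthetic = mk(syntheticSpec, "synthetic"),
    excludeChannels = as.character(raw$excludeChannels %||% character()),
    seed = as.integer(raw$seed %||% 1L)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a run manifest
#'
#' Records everything needed to reproduce a pipeline run: config
#' hash, seeds, package version, input file hashes, output paths and
#' a timestamp. Two runs with identical manifests produce identical
#' outputs.
#'
#' @param config the resolved configuration list.
#' @param inputs character vector of input file paths (hashed).
#' @param outputs character vector of output paths.
#' @param seed master seed of the run.
#' @return list; write with [writeManifest()].
#' @export
runManifest <- function(config, inputs = character(),
                        outputs = character(), seed = 1L) {
  list(
    package = as.character(utils::packageVersion("hfoLSTM")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    configHash = dataHash(config),
    inputs = if (length(inputs))
      stats::setNames(as.list(tools::md5sum(inputs)), inputs) else list(),
    outputs = as.list(outputs)
  )
}

#' @rdname runManifest
#' @param manifest a manifest list.
#' @param path output JSON path.
#' @export
writeManifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Pipeline step: simulate synthetic subjects to EDF fixtures
#'
#' @param outDir output directory.
#' @param nSubjects number of subjects.
#' @param config resolved config list from [readPipelineConfig()].
#' @return data.frame of written files, invisibly.
#' @export
cmdSimulate <- function(outDir, nSubjects = 1L,
                        config = readPipelineConfig()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  files <- lapply(seq_len(nSubjects), function(k) {
    sub <- generateSubject(config$synthetic, k)
    writeFixture(sub$record, sub$log,
                 file.path(outDir, paste0("S", k)))
  })
  out <- data.frame(subject = paste0("S", seq_len(nSubjects)),
                    edf = vapply(files, `[`, "", 1L),
                    log = vapply(files, `[`, "", 2L))
  writeManifest(runManifest(config, outputs = unlist(files),
                            seed = config$synthetic$seed),
                file.path(outDir, "manifest.json"))
  invisible(out)
}

#' Pipeline step: detect candidates in EDF recordings
#'
#' Reads each EDF, runs preprocessing, the band spectrogram and the
#' threshold detector, and writes one candidate CSV (and BED-like
#' interval file) per input. Deterministic: rerunning with the same
#' inputs and config reproduces the outputs byte for byte.
#'
#' @param edfPaths character vector of EDF files.
#' @param outDir output directory.
#' @param config resolved config list from [readPipelineConfig()].
#' @return data.frame mapping inputs to candidate CSVs, invisibly.
#' @export
cmdDetect <- function(edfPaths, outDir, config = readPipelineConfig()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  outs <- character()
  for (p in edfPaths) {
    rec <- readEDF(p, exclude = config$excludeChannels)
    det <- detectRecord(rec, config$detector, config$preprocess)
    stem <- sub("\\.edf$", "", basename(p), ignore.case = TRUE)
    csv <- file.path(outDir, paste0(stem, "_candidates.csv"))
    utils::write.csv(det$candidates, csv, row.names = FALSE)
    writeCandidateBed(det$candidates,
                      file.path(outDir, paste0(stem, "_events.bed")),
                      binDuration(det$rel))
    outs <- c(outs, csv)
  }
  writeManifest(runManifest(config, inputs = edfPaths, outputs = outs,
                            seed = config$seed),
                file.path(outDir, "manifest.json"))
  invisible(data.frame(input = edfPaths, candidates = outs))
}

#' Pipeline step: run a training/evaluation scenario end to end
#'
#' Simulates the ground-truth dataset (training site plus optional
#' held-out site), runs [runExperiment()] and writes the metric table
#' as CSV (one row per subject and metric, mean and SD columns),
#' shaped like the per-subject report tables of the validation
#' scenarios.
#'
#' @param scenario scenario name, see [runExperiment()].
#' @param outDir output directory.
#' @param nSubjects training-site subjects.
#' @param nHoldout held-out-site subjects (`cross_site` only).
#' @param nPerClass ground-truth events per class per subject.
#' @param nTrain,nTest,nRandomizations split sizes.
#' @param config resolved config list.
#' @return the [runExperiment()] result, invisibly.
#' @export
cmdExperiment <- function(scenario, outDir, nSubjects = 3L, nHoldout = 0L,
                          nPerClass = 200L, nTrain = 100L, nTest = 100L,
                          nRandomizations = 3L,
                          config = readPipelineConfig()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  spec <- config$synthetic
  sim <- simulateGroundTruth(nSubjects, nPerClass, spec = spec,
                             detector = config$detector,
                             seed = config$seed)
  gtHold <- NULL
  if (scenario == "cross_site") {
    specB <- spec
    specB$seed <- spec$seed + 5000L
    simB <- simulateGroundTruth(nHoldout, nPerClass, spec = specB,
                                detector = config$detector,
                                subjectPrefix = "B",
                                seed = config$seed + 5000L)
    gtHold <- simB$gt
  }
  res <- runExperiment(scenario, sim$gt, nTrain = nTrain, nTest = nTest,
                       nRandomizations = nRandomizations,
                       config = config$lstm, gtHoldout = gtHold,
                       seed = config$seed)
  csv <- file.path(outDir, paste0(scenario, "_metrics.csv"))
  utils::write.csv(res$table, csv, row.names = FALSE)
  writeManifest(runManifest(config, outputs = csv, seed = config$seed),
                file.path(outDir, "manifest.json"))
  invisible(res)
}
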
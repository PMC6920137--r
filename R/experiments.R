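# Training/evaluation scenarios: within-subject, between-subjects,
# global (pooled) and cross-site validation, plus parameter sweeps.

.trainOn <- function(gt, idx, config, seed) {
  cfg <- config; cfg$seed <- seed
  model <- buildLstm(do.call(lstmConfig, cfg[names(formals(lstmConfig))]))
  info <- eventInfo(gt)
  trainLstm(model, eventFeatures(gt)[, , idx, drop = FALSE],
            info$label[idx], seed = seed)
}

.evalOn <- function(model, gt, idx) {
  info <- eventInfo(gt)
  pred <- predict(model, eventFeatures(gt)[, , idx, drop = FALSE])
  evaluatePredictions(info$label[idx], pred$label)
}

.subjectIdx <- function(gt, idx, subject) {
  idx[eventInfo(gt)$subject[idx] == subject]
}

#' Run a training/evaluation scenario
#'
#' The four validation scenarios over a ground-truth set:
#' * `within_subject`: train and test inside each subject.
#' * `between_subjects`: train on one subject, test on every other
#'   (and itself), giving a subjects x subjects accuracy grid whose
#'   diagonal is the within-subject result.
#' * `global`: pool training events of all subjects; evaluate per
#'   subject and pooled.
#' * `cross_site`: as `global`, additionally evaluating each subject
#'   of a held-out second ground-truth set (`gtHoldout`) that
#'   contributes no training events.
#'
#' Every scenario repeats over `nRandomizations` independent
#' train/test splits and reports mean +/- SD of each metric.
#'
#' @param scenario one of the four scenario names.
#' @param gt a [GroundTruthSet-class] (the training site).
#' @param nTrain,nTest events per class per subject for training and
#'   testing (defaults 500/500).
#' @param nRandomizations independent splits (default 10).
#' @param config an [lstmConfig()].
#' @param gtHoldout held-out-site [GroundTruthSet-class] (required for
#'   `cross_site`).
#' @param seed master seed for splitting and training.
#' @return list of class `"ExperimentResult"`: `scenario`, `perSubject`
#'   (aggregated metric tables), `reports` (raw per-randomization
#'   [EvalReport-class]s), `table` (long data.frame subject x metric
#'   with mean/sd), and for `between_subjects` an `accGrid` of mean
#'   accuracies (train subjects in columns, test subjects in rows).
#' @export
runExperiment <- function(scenario = c("within_subject", "between_subjects",
                                       "global", "cross_site"),
                          gt, nTrain = 500L, nTest = 500L,
                          nRandomizations = 10L, config = lstmConfig(),
                          gtHoldout = NULL, seed = 1L) {
  scenario <- match.arg(scenario)
  if (scenario == "cross_site" && is.null(gtHoldout))
    stop("scenario error: cross_site requires a held-out ground-truth set")
  splits <- makeSplits(gt, nTrain, nTest, nRandomizations, seed = seed)
  subjects <- unique(eventInfo(gt)$subject)
  reports <- list()

  if (scenario == "within_subject") {
    for (sj in subjects) {
      reports[[sj]] <- lapply(seq_len(nRandomizations), function(r) {
        model <- .trainOn(gt, .subjectIdx(gt, splits[[r]]$train, sj),
                          config, seed + 100L * r)
        .evalOn(model, gt, .subjectIdx(gt, splits[[r]]$test, sj))
      })
    }
  } else if (scenario == "between_subjects") {
    for (trainSj in subjects) {
      for (r in seq_len(nRandomizations)) {
        model <- .trainOn(gt, .subjectIdx(gt, splits[[r]]$train, trainSj),
                          config, seed + 100L * r)
        for (testSj in subjects) {
          key <- paste(testSj, "on", trainSj)
          reports[[key]][[r]] <-
            .evalOn(model, gt, .subjectIdx(gt, splits[[r]]$test, testSj))
        }
      }
    }
  } else {                                # global / cross_site
    holdSplits <- if (!is.null(gtHoldout))
      makeSplits(gtHoldout, 0L, nTest, nRandomizations, seed = seed + 1L)
    for (r in seq_len(nRandomizations)) {
      model <- .trainOn(gt, splits[[r]]$train, config, seed + 100L * r)
      for (sj in subjects)
        reports[[sj]][[r]] <-
          .evalOn(model, gt, .subjectIdx(gt, splits[[r]]$test, sj))
      reports[["pooled"]][[r]] <- .evalOn(model, gt, splits[[r]]$test)
      if (scenario == "cross_site") {
        for (sj in unique(eventInfo(gtHoldout)$subject))
          reports[[sj]][[r]] <- .evalOn(
            model, gtHoldout,
            .subjectIdx(gtHoldout, holdSplits[[r]]$test, sj))
      }
    }
  }

  perSubject <- lapply(reports, aggregateReports)
  tab <- do.call(rbind, lapply(names(perSubject), function(nm) {
    cbind(subject = nm, perSubject[[nm]])
  }))
  res <- list(scenario = scenario, perSubject = perSubject,
              reports = reports, table = tab)
  if (scenario == "between_subjects") {
    grid <- matrix(NA_real_, length(subjects), length(subjects),
                   dimnames = list(test = subjects, train = subjects))
    for (trainSj in subjects)
      for (testSj in subjects) {
        agg <- perSubject[[paste(testSj, "on", trainSj)]]
        grid[testSj, trainSj] <- agg$mean[agg$metric == "accuracy"]
      }
    res$accGrid <- grid
  }
  class(res) <- "ExperimentResult"
  res
}

#' @export
print.ExperimentResult <- function(x, ...) {
  cat("ExperimentResult:", x$scenario, "\n")
  acc <- x$table[x$table$metric == "accuracy", ]
  print(data.frame(subject = acc$subject,
                   accuracy = sprintf("%.1f (%.1f)", acc$mean, acc$sd)),
        row.names = FALSE)
  invisible(x)
}

#' Parameter and architecture sweeps
#'
#' Repeats the `global` scenario over a grid of one hyperparameter
#' (`"hiddenUnits"`, `"nIterations"` or `"nTrain"`) or over the four
#' architecture variants (`"architecture"`: one LSTM, two LSTMs, two
#' LSTMs with 0.2 dropout, bidirectional LSTM), reporting the pooled
#' accuracy and per-class sensitivity of each setting.
#'
#' @param gt a [GroundTruthSet-class].
#' @param what which axis to sweep.
#' @param values vector of parameter values (ignored for
#'   `"architecture"`).
#' @param nTrain,nTest,nRandomizations,config,seed as in
#'   [runExperiment()].
#' @return data.frame: one row per setting with mean (sd) columns for
#'   pooled accuracy and per-class sensitivity.
#' @export
runSweep <- function(gt, what = c("hiddenUnits", "nIterations", "nTrain",
                                  "architecture"),
                     values = NULL, nTrain = 500L, nTest = 500L,
                     nRandomizations = 10L, config = lstmConfig(),
                     seed = 1L) {
  what <- match.arg(what)
  settings <- if (what == "architecture") {
    list(oneLstm = list(layers = 1L, bidirectional = FALSE, dropout = 0),
         twoLstm = list(layers = 2L, bidirectional = FALSE, dropout = 0),
         twoLstmDropout = list(layers = 2L, bidirectional = FALSE,
                               dropout = 0.2),
         biLstm = list(layers = 1L, bidirectional = TRUE, dropout = 0))
  } else {
    stopifnot(!is.null(values))
    stats::setNames(as.list(values), as.character(values))
  }
  rows <- lapply(names(settings), function(nm) {
    cfg <- config
    nTr <- nTrain
    if (what == "architecture") cfg[names(settings[[nm]])] <- settings[[nm]]
    else if (what == "nTrain") nTr <- settings[[nm]]
    else cfg[[what]] <- settings[[nm]]
    res <- runExperiment("global", gt, nTrain = nTr, nTest = nTest,
                         nRandomizations = nRandomizations, config = cfg,
                         seed = seed)
    agg <- res$perSubject$pooled
    out <- data.frame(setting = nm, stringsAsFactors = FALSE)
    for (m in c("accuracy", paste0("sens_", eventClasses()))) {
      out[[paste0(m, "_mean")]] <- agg$mean[agg$metric == m]
      out[[paste0(m, "_sd")]] <- agg$sd[agg$metric == m]
    }
    out
  })
  do.call(rbind, rows)
}
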
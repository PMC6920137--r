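# Multi-class metrics: confusion counts, total accuracy, per-class
# sensitivity and specificity, and mean +/- SD aggregation.

#' 4x4 confusion counts
#'
#' `counts[i, j]` = number of events with true class i predicted as
#' class j, classes in the fixed order of [eventClasses()].
#'
#' @param trueLabels,predictedLabels equal-length vectors of class
#'   labels (character or factor over the four classes).
#' @return 4x4 integer matrix with dimnames.
#' @export
confusionCounts <- function(trueLabels, predictedLabels) {
  if (length(trueLabels) != length(predictedLabels))
    stop("input error: label vectors differ in length")
  cls <- eventClasses()
  tl <- factor(as.character(trueLabels), levels = cls)
  pl <- factor(as.character(predictedLabels), levels = cls)
  if (anyNA(tl) || anyNA(pl))
    stop("input error: labels outside the four event classes")
  unclass(table(true = tl, predicted = pl))
}

#' Metrics from a confusion matrix
#'
#' Applies the standard multi-class formulas: total accuracy
#' `Acc = 100 sum_i TP(i) / sum_i P(i)`, per-class sensitivity
#' `Sens(i) = 100 TP(i)/P(i)` and specificity
#' `Spec(i) = 100 (1 - FP(i)/N(i))`, where P(i)/N(i) are the positive
#' and negative case counts, TP(i) the diagonal entry and FP(i) the
#' off-diagonal column sum for class i. A class with `P(i) = 0`
#' reports sensitivity `NA` (e.g. a subject with no RonS events).
#'
#' @param confusion 4x4 nonnegative count matrix (rows = true class).
#' @return An [EvalReport-class].
#' @export
#' @examples
#' cm <- diag(c(100, 100, 100, 100))
#' totalAccuracy(computeMetrics(cm))   # 100
computeMetrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (!all(dim(confusion) == c(4L, 4L)) || any(confusion < 0))
    stop("confusion must be a nonnegative 4x4 matrix")
  if (sum(confusion) == 0) stop("empty-report error: all counts are zero")
  cls <- eventClasses()
  dimnames(confusion) <- list(true = cls, predicted = cls)
  P <- rowSums(confusion)
  TP <- diag(confusion)
  FP <- colSums(confusion) - TP
  N <- sum(P) - P
  sens <- ifelse(P > 0, 100 * TP / P, NA_real_)
  spec <- ifelse(N > 0, 100 * (1 - FP / N), NA_real_)
  perClass <- data.frame(
    class = cls, P = as.numeric(P), N = as.numeric(N),
    TP = as.numeric(TP), FP = as.numeric(FP),
    sens = as.numeric(sens), spec = as.numeric(spec),
    stringsAsFactors = FALSE
  )
  new("EvalReport", confusion = confusion, perClass = perClass,
      accuracy = 100 * sum(TP) / sum(P))
}

#' Evaluate predictions directly
#'
#' Convenience: [confusionCounts()] then [computeMetrics()].
#'
#' @inheritParams confusionCounts
#' @return An [EvalReport-class].
#' @export
evaluatePredictions <- function(trueLabels, predictedLabels) {
  computeMetrics(confusionCounts(trueLabels, predictedLabels))
}

#' Aggregate reports over randomizations
#'
#' Arithmetic mean and sample SD (n - 1 denominator) of every metric
#' across a list of reports; `NA` cells (classes with no positive
#' cases) propagate as `NA`. With a single report the SDs are `NA`.
#'
#' @param reports list of [EvalReport-class] objects with identical
#'   class structure.
#' @return data.frame with rows `accuracy`, `sens_<class>`,
#'   `spec_<class>` and columns `mean`, `sd`, `n`.
#' @export
aggregateReports <- function(reports) {
  stopifnot(length(reports) >= 1L)
  cls <- eventClasses()
  vals <- vapply(reports, function(r) {
    pc <- perClassMetrics(r)
    c(accuracy = totalAccuracy(r),
      stats::setNames(pc$sens, paste0("sens_", cls)),
      stats::setNames(pc$spec, paste0("spec_", cls)))
  }, numeric(1L + 2L * length(cls)))
  vals <- matrix(vals, ncol = length(reports),
                 dimnames = list(c("accuracy", paste0("sens_", cls),
                                   paste0("spec_", cls)), NULL))
  data.frame(
    metric = rownames(vals),
    mean = rowMeans(vals),
    sd = apply(vals, 1L, function(v)
      if (length(v) > 1L) stats::sd(v) else NA_real_),
    n = length(reports),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
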
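#' @import methods
NULL

#' Event classes recognised by the pipeline
#'
#' The four mutually exclusive event classes, in the fixed order used
#' everywhere in the package (confusion matrices, softmax outputs,
#' argmax tie-breaking): spike, ripple-on-spike, ripple, baseline.
#'
#' @return Character vector of length 4.
#' @export
#' @examples
#' eventClasses()
eventClasses <- function() c("spike", "rons", "ripple", "baseline")

#' Multichannel intracranial EEG record
#'
#' Holds a channels-by-timepoints voltage matrix (microvolts) together
#' with the sampling rate, channel labels and a subject identifier.
#' Channels must all have the same length (rows of one matrix) and the
#' sampling rate must be at least 500 Hz so that the ripple bands (up
#' to 236 Hz) lie below Nyquist. Missing samples (NA) are permitted on
#' construction and removed by [removeMissing()].
#'
#' @slot samples numeric matrix, channels x timepoints, in microvolts.
#' @slot fs sampling rate in Hz (>= 500).
#' @slot channelLabels character vector, one label per channel.
#' @slot subjectId single string identifying the subject.
#' @slot log character vector of processing-log lines.
#'
#' @seealso [EegRecord()] constructor, [removeMissing()],
#'   [highpassZeroPhase()], [notchFilter()]
#' @export
setClass("EegRecord",
  representation(
    samples = "matrix",
    fs = "numeric",
    channelLabels = "character",
    subjectId = "character",
    log = "character"
  )
)

setValidity("EegRecord", function(object) {
  msg <- character()
  if (!is.numeric(object@samples))
    msg <- c(msg, "'samples' must be a numeric matrix")
  if (length(object@fs) != 1L || is.na(object@fs) || object@fs < 500)
    msg <- c(msg, "'fs' must be a single value >= 500 Hz (ripple bands need Nyquist > 236 Hz)")
  if (length(object@channelLabels) != nrow(object@samples))
    msg <- c(msg, "one channel label per row of 'samples' is required")
  if (anyDuplicated(object@channelLabels))
    msg <- c(msg, "channel labels must be unique")
  if (length(object@subjectId) != 1L)
    msg <- c(msg, "'subjectId' must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct an EegRecord
#'
#' @param samples numeric matrix (channels x timepoints) or a numeric
#'   vector for a single channel, in microvolts.
#' @param fs sampling rate in Hz; must be >= 500.
#' @param channelLabels optional channel labels (default `"ch1"`, ...).
#' @param subjectId subject identifier string.
#'
#' @return An [EegRecord-class] object.
#' @export
#' @examples
#' rec <- EegRecord(matrix(rnorm(2000), nrow = 2), fs = 500)
#' nChannels(rec)
EegRecord <- function(samples, fs, channelLabels = NULL, subjectId = "s1") {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1L)
  if (is.null(channelLabels))
    channelLabels <- paste0("ch", seq_len(nrow(samples)))
  new("EegRecord",
    samples = samples, fs = as.numeric(fs),
    channelLabels = as.character(channelLabels),
    subjectId = as.character(subjectId), log = character()
  )
}

#' The eight-band spectral partition
#'
#' The detector's fixed set of eight frequency bands: theta (4-8 Hz),
#' alpha (8-13), beta (13-30), gamma1 (30-56), gamma2 (64-116),
#' rip1 (124-176), rip2 (184-196) and rip3 (204-236 Hz). The gaps
#' around 60, 120, 180 and 200 Hz avoid mains interference and its
#' harmonics. Band membership on the frequency grid is half-open,
#' `[low, high)`, so a shared printed edge (e.g. 8 Hz) belongs to the
#' upper band.
#'
#' @return data.frame with columns `name`, `low`, `high` (Hz).
#' @export
#' @examples
#' defaultBandSet()
defaultBandSet <- function() {
  data.frame(
    name = c("theta", "alpha", "beta", "gamma1", "gamma2",
             "rip1", "rip2", "rip3"),
    low  = c(4, 8, 13, 30, 64, 124, 184, 204),
    high = c(8, 13, 30, 56, 116, 176, 196, 236),
    stringsAsFactors = FALSE
  )
}

.checkBandSet <- function(bs) {
  ok <- is.data.frame(bs) && nrow(bs) == 8L &&
    all(c("name", "low", "high") %in% names(bs)) &&
    all(bs$low < bs$high) && !is.unsorted(c(rbind(bs$low, bs$high)))
  if (!ok) stop("invalid band set: need 8 ordered, non-overlapping bands")
  invisible(bs)
}

#' Band-averaged power spectrogram
#'
#' Per-channel, per-band, per-time-bin spectral power: the short-time
#' spectrogram averaged within each of the eight bands of the band set.
#' Time bins are non-overlapping windows of `binDuration` seconds
#' (default 0.25 s, giving 4 Hz frequency resolution).
#'
#' @slot power nonnegative array, channels x 8 bands x T bins.
#' @slot binDuration bin length in seconds.
#' @slot bandSet data.frame as returned by [defaultBandSet()].
#' @slot t0 start time (s) of the first bin.
#' @slot channelLabels character vector of channel names.
#'
#' @seealso [bandSpectrogram()], [normalizeSpectrogram()]
#' @export
setClass("BandSpectrogram",
  representation(
    power = "array", binDuration = "numeric",
    bandSet = "data.frame", t0 = "numeric",
    channelLabels = "character"
  )
)

setValidity("BandSpectrogram", function(object) {
  msg <- character()
  d <- dim(object@power)
  if (length(d) != 3L || d[2] != 8L)
    msg <- c(msg, "'power' must be a channels x 8 x T array")
  if (any(object@power < 0, na.rm = TRUE))
    msg <- c(msg, "band power must be nonnegative")
  if (length(object@binDuration) != 1L || object@binDuration <= 0)
    msg <- c(msg, "'binDuration' must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Baseline-normalised (relative) spectrogram
#'
#' Band powers divided by the per-(channel, band) baseline power, the
#' detector's working representation: values are dimensionless ratios
#' whose log-distribution mode sits near 0 (ratio near 1) for ongoing
#' background activity.
#'
#' @slot relPower nonnegative ratio array, channels x 8 x T.
#' @slot binDuration bin length in seconds.
#' @slot bandSet band definition data.frame.
#' @slot baseline channels x 8 matrix of baseline powers (positive).
#' @slot t0 start time (s) of the first bin.
#' @slot channelLabels character vector of channel names.
#'
#' @seealso [normalizeSpectrogram()], [detectCandidates()]
#' @export
setClass("RelativeSpectrogram",
  representation(
    relPower = "array", binDuration = "numeric",
    bandSet = "data.frame", baseline = "matrix", t0 = "numeric",
    channelLabels = "character"
  )
)

setValidity("RelativeSpectrogram", function(object) {
  msg <- character()
  d <- dim(object@relPower)
  if (length(d) != 3L || d[2] != 8L)
    msg <- c(msg, "'relPower' must be a channels x 8 x T array")
  if (any(object@relPower < 0, na.rm = TRUE))
    msg <- c(msg, "relative power must be nonnegative")
  if (any(object@baseline <= 0))
    msg <- c(msg, "baseline powers must be strictly positive")
  if (!all(dim(object@baseline) == d[1:2]))
    msg <- c(msg, "'baseline' must be channels x 8")
  if (length(msg)) msg else TRUE
})

#' Balanced ground-truth event set
#'
#' Labelled 8-band x 3-bin feature matrices grouped by subject and
#' class, the unit consumed by the LSTM classifier. Within a subject
#' each class cell holds at most the configured number of events;
#' cells that could not be filled are flagged short (a subject may
#' genuinely lack a class, e.g. no ripple-on-spike events).
#'
#' @slot features numeric array, 8 x 3 x N (band x time-step x event).
#' @slot info data.frame with one row per event: `subject`, `channel`,
#'   `bin`, `time_s`, `label` (factor over [eventClasses()]).
#'
#' @seealso [assembleGroundTruth()], [makeSplits()]
#' @export
setClass("GroundTruthSet",
  representation(features = "array", info = "data.frame")
)

setValidity("GroundTruthSet", function(object) {
  msg <- character()
  d <- dim(object@features)
  if (length(d) != 3L || d[1] != 8L || d[2] != 3L)
    msg <- c(msg, "'features' must be an 8 x 3 x N array")
  if (nrow(object@info) != d[3])
    msg <- c(msg, "'info' must have one row per event")
  need <- c("subject", "channel", "bin", "label")
  if (!all(need %in% names(object@info)))
    msg <- c(msg, "'info' must have subject, channel, bin, label columns")
  else {
    if (!all(levels(object@info$label) == eventClasses()))
      msg <- c(msg, "label levels must be the four event classes in order")
    if (anyDuplicated(object@info[, need]))
      msg <- c(msg, "duplicate (subject, channel, bin, label) entries")
  }
  if (length(msg)) msg else TRUE
})

#' Bidirectional LSTM event classifier
#'
#' A small sequence classifier: sequence input (8 features over 3 time
#' steps) -> one or two (bi)LSTM layers (optionally followed by
#' dropout) -> fully connected layer -> softmax over the four event
#' classes. Weights live in `params`; `config` records the
#' architecture and training hyperparameters; `manifest` records the
#' data hash and seed of the last training run for reproducibility.
#'
#' @slot config list, see [lstmConfig()].
#' @slot params list of weight matrices (layers + fully connected).
#' @slot classes character vector of output classes, fixed order.
#' @slot trained logical flag.
#' @slot history numeric vector of per-iteration training losses.
#' @slot manifest list (seed, data hash, iterations).
#'
#' @seealso [buildLstm()], [trainLstm()], [predict,LstmClassifier-method]
#' @export
setClass("LstmClassifier",
  representation(
    config = "list", params = "list", classes = "character",
    trained = "logical", history = "numeric", manifest = "list"
  )
)

#' Multi-class evaluation report
#'
#' A 4x4 confusion matrix (rows = true class, columns = predicted)
#' with the derived per-class counts and metrics: P(i), N(i), TP(i),
#' FP(i), sensitivity Sens(i) = 100 TP(i)/P(i), specificity
#' Spec(i) = 100 (1 - FP(i)/N(i)), and total accuracy
#' Acc = 100 sum(TP)/sum(P). Classes with no positive cases report
#' sensitivity as NA.
#'
#' @slot confusion 4x4 count matrix.
#' @slot perClass data.frame: class, P, N, TP, FP, sens, spec.
#' @slot accuracy total accuracy in percent.
#'
#' @seealso [computeMetrics()], [aggregateReports()]
#' @export
setClass("EvalReport",
  representation(
    confusion = "matrix", perClass = "data.frame", accuracy = "numeric"
  )
)

setValidity("EvalReport", function(object) {
  msg <- character()
  if (!all(dim(object@confusion) == c(4L, 4L)))
    msg <- c(msg, "'confusion' must be 4x4")
  if (any(object@confusion < 0))
    msg <- c(msg, "confusion counts must be nonnegative")
  if (length(msg)) msg else TRUE
})
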
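# Accessor generics and show methods for the package's S4 classes.

#' @describeIn EegRecord-class voltage matrix (channels x timepoints)
#' @param object an object of the documented class
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))
#' @describeIn EegRecord-class sampling rate in Hz
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @describeIn EegRecord-class channel labels
#' @export
setGeneric("channelLabels", function(object) standardGeneric("channelLabels"))
#' @describeIn EegRecord-class subject identifier
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @describeIn EegRecord-class number of channels
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))
#' @describeIn EegRecord-class record duration in seconds
#' @export
setGeneric("recordDuration", function(object) standardGeneric("recordDuration"))
#' @describeIn EegRecord-class processing-log lines accumulated so far
#' @export
setGeneric("processingLog", function(object) standardGeneric("processingLog"))

#' @describeIn BandSpectrogram-class power array (channels x 8 x T)
#' @param object an object of the documented class
#' @export
setGeneric("bandPower", function(object) standardGeneric("bandPower"))
#' @describeIn BandSpectrogram-class band definition table
#' @export
setGeneric("bandSet", function(object) standardGeneric("bandSet"))
#' @describeIn BandSpectrogram-class time-bin duration (s)
#' @export
setGeneric("binDuration", function(object) standardGeneric("binDuration"))

#' @describeIn RelativeSpectrogram-class ratio array (channels x 8 x T)
#' @param object an object of the documented class
#' @export
setGeneric("relPower", function(object) standardGeneric("relPower"))
#' @describeIn RelativeSpectrogram-class baseline power matrix
#' @export
setGeneric("baselinePower", function(object) standardGeneric("baselinePower"))

#' @describeIn GroundTruthSet-class feature array (8 x 3 x N)
#' @param object an object of the documented class
#' @export
setGeneric("eventFeatures", function(object) standardGeneric("eventFeatures"))
#' @describeIn GroundTruthSet-class per-event metadata data.frame
#' @export
setGeneric("eventInfo", function(object) standardGeneric("eventInfo"))
#' @describeIn GroundTruthSet-class per-(subject, class) event counts
#' @export
setGeneric("eventCounts", function(object) standardGeneric("eventCounts"))

#' @describeIn EvalReport-class 4x4 confusion count matrix
#' @param object an object of the documented class
#' @export
setGeneric("confusion", function(object) standardGeneric("confusion"))
#' @describeIn EvalReport-class per-class metric table
#' @export
setGeneric("perClassMetrics", function(object) standardGeneric("perClassMetrics"))
#' @describeIn EvalReport-class total accuracy (%)
#' @export
setGeneric("totalAccuracy", function(object) standardGeneric("totalAccuracy"))

#' @rdname EegRecord-class
#' @export
setMethod("samples", "EegRecord", function(object) object@samples)
#' @rdname EegRecord-class
#' @export
setMethod("samplingRate", "EegRecord", function(object) object@fs)
#' @rdname EegRecord-class
#' @export
setMethod("channelLabels", "EegRecord", function(object) object@channelLabels)
#' @rdname EegRecord-class
#' @export
setMethod("subjectId", "EegRecord", function(object) object@subjectId)
#' @rdname EegRecord-class
#' @export
setMethod("nChannels", "EegRecord", function(object) nrow(object@samples))
#' @rdname EegRecord-class
#' @export
setMethod("recordDuration", "EegRecord",
          function(object) ncol(object@samples) / object@fs)
#' @rdname EegRecord-class
#' @export
setMethod("processingLog", "EegRecord", function(object) object@log)

setMethod("show", "EegRecord", function(object) {
  cat(sprintf(
    "EegRecord '%s': %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
    object@subjectId, nrow(object@samples), ncol(object@samples),
    object@fs, ncol(object@samples) / object@fs
  ))
  if (anyNA(object@samples)) cat("  contains missing samples\n")
})

#' @rdname BandSpectrogram-class
#' @export
setMethod("bandPower", "BandSpectrogram", function(object) object@power)
#' @rdname BandSpectrogram-class
#' @export
setMethod("bandSet", "BandSpectrogram", function(object) object@bandSet)
#' @rdname BandSpectrogram-class
#' @export
setMethod("binDuration", "BandSpectrogram", function(object) object@binDuration)

setMethod("show", "BandSpectrogram", function(object) {
  d <- dim(object@power)
  cat(sprintf(
    "BandSpectrogram: %d channel(s) x %d bands x %d bins of %g s\n",
    d[1], d[2], d[3], object@binDuration
  ))
})

#' @rdname RelativeSpectrogram-class
#' @export
setMethod("relPower", "RelativeSpectrogram", function(object) object@relPower)
#' @rdname RelativeSpectrogram-class
#' @export
setMethod("baselinePower", "RelativeSpectrogram", function(object) object@baseline)
#' @rdname RelativeSpectrogram-class
#' @export
setMethod("bandSet", "RelativeSpectrogram", function(object) object@bandSet)
#' @rdname RelativeSpectrogram-class
#' @export
setMethod("binDuration", "RelativeSpectrogram",
          function(object) object@binDuration)

setMethod("show", "RelativeSpectrogram", function(object) {
  d <- dim(object@relPower)
  cat(sprintf(
    "RelativeSpectrogram: %d channel(s) x %d bands x %d bins of %g s\n",
    d[1], d[2], d[3], object@binDuration
  ))
})

#' @rdname GroundTruthSet-class
#' @export
setMethod("eventFeatures", "GroundTruthSet", function(object) object@features)
#' @rdname GroundTruthSet-class
#' @export
setMethod("eventInfo", "GroundTruthSet", function(object) object@info)
#' @rdname GroundTruthSet-class
#' @export
setMethod("eventCounts", "GroundTruthSet", function(object)
  table(object@info$subject, object@info$label))

setMethod("show", "GroundTruthSet", function(object) {
  cat(sprintf("GroundTruthSet: %d events, %d subject(s)\n",
              nrow(object@info), length(unique(object@info$subject))))
  print(eventCounts(object))
})

setMethod("show", "LstmClassifier", function(object) {
  cfg <- object@config
  cat(sprintf(
    "LstmClassifier: %s%d LSTM layer(s), %d hidden units, dropout %g\n",
    if (cfg$bidirectional) "bidirectional, " else "", cfg$layers,
    cfg$hiddenUnits, cfg$dropout
  ))
  cat(sprintf("  trained: %s (%d parameters)\n",
              if (object@trained) "yes" else "no", nParams(object)))
})

#' @rdname EvalReport-class
#' @export
setMethod("confusion", "EvalReport", function(object) object@confusion)
#' @rdname EvalReport-class
#' @export
setMethod("perClassMetrics", "EvalReport", function(object) object@perClass)
#' @rdname EvalReport-class
#' @export
setMethod("totalAccuracy", "EvalReport", function(object) object@accuracy)

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: total accuracy %.2f%%\n", object@accuracy))
  print(round(object@perClass[, c("class", "sens", "spec")], 2))
})
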
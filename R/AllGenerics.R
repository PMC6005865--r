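## Generics and accessors.  Slot access from user code should go through
## these rather than @.

#' @rdname SensorLayout-class
#' @param object,x a \code{SensorLayout}, \code{EpochSet},
#'   \code{ContinuousRecording}, \code{ForwardModel} or \code{SourceEstimate}.
#' @export
setGeneric("sensorPositions", function(object) standardGeneric("sensorPositions"))
#' @rdname SensorLayout-class
#' @export
setGeneric("pairMap", function(object) standardGeneric("pairMap"))
#' @rdname SensorLayout-class
#' @export
setGeneric("adjacency", function(object) standardGeneric("adjacency"))
#' @rdname SensorLayout-class
#' @export
setGeneric("sensorGroups", function(object) standardGeneric("sensorGroups"))
#' @rdname ForwardModel-class
#' @param object a \code{ForwardModel}.
#' @export
setGeneric("leadfield", function(object) standardGeneric("leadfield"))
#' @rdname ForwardModel-class
#' @export
setGeneric("gridCoords", function(object) standardGeneric("gridCoords"))
#' @rdname ForwardModel-class
#' @export
setGeneric("regionLabels", function(object) standardGeneric("regionLabels"))
#' @rdname EpochSet-class
#' @export
setGeneric("epochData", function(object) standardGeneric("epochData"))
#' @rdname EpochSet-class
#' @export
setGeneric("epochTimes", function(object) standardGeneric("epochTimes"))
#' @rdname EpochSet-class
#' @export
setGeneric("conditions", function(object) standardGeneric("conditions"))
#' @rdname EpochSet-class
#' @export
setGeneric("covariates", function(object) standardGeneric("covariates"))
#' @rdname ContinuousRecording-class
#' @export
setGeneric("recordingData", function(object) standardGeneric("recordingData"))
#' @rdname ContinuousRecording-class
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname ContinuousRecording-class
#' @export
setGeneric("triggers", function(object) standardGeneric("triggers"))
#' @rdname ContinuousRecording-class
#' @export
setGeneric("baselineIntervals", function(object) standardGeneric("baselineIntervals"))
#' @rdname SourceEstimate-class
#' @export
setGeneric("sourceCurrents", function(object) standardGeneric("sourceCurrents"))

#' @rdname SensorLayout-class
#' @export
setMethod("sensorPositions", "SensorLayout", function(object) object@positions)
#' @rdname SensorLayout-class
#' @export
setMethod("pairMap", "SensorLayout", function(object) object@pairMap)
#' @rdname SensorLayout-class
#' @export
setMethod("adjacency", "SensorLayout", function(object) object@adjacency)
#' @rdname SensorLayout-class
#' @export
setMethod("sensorGroups", "SensorLayout", function(object) object@groups)
#' @rdname ForwardModel-class
#' @export
setMethod("leadfield", "ForwardModel", function(object) object@leadfield)
#' @rdname ForwardModel-class
#' @export
setMethod("gridCoords", "ForwardModel", function(object) object@gridCoords)
#' @rdname ForwardModel-class
#' @export
setMethod("regionLabels", "ForwardModel", function(object) object@regionLabels)
#' @rdname ForwardModel-class
#' @export
setMethod("adjacency", "ForwardModel", function(object) object@gridAdjacency)
#' @rdname EpochSet-class
#' @export
setMethod("epochData", "EpochSet", function(object) object@data)
#' @rdname EpochSet-class
#' @export
setMethod("epochTimes", "EpochSet", function(object) object@times)
#' @rdname EpochSet-class
#' @export
setMethod("conditions", "EpochSet", function(object) object@conditions)
#' @rdname EpochSet-class
#' @export
setMethod("covariates", "EpochSet", function(object) object@covariates)
#' @rdname EpochSet-class
#' @export
setMethod("samplingRate", "EpochSet", function(object) object@sfreq)
#' @rdname ContinuousRecording-class
#' @export
setMethod("recordingData", "ContinuousRecording", function(object) object@data)
#' @rdname ContinuousRecording-class
#' @export
setMethod("samplingRate", "ContinuousRecording", function(object) object@sfreq)
#' @rdname ContinuousRecording-class
#' @export
setMethod("triggers", "ContinuousRecording", function(object) object@triggers)
#' @rdname ContinuousRecording-class
#' @export
setMethod("baselineIntervals", "ContinuousRecording", function(object) object@baselineIntervals)
#' @rdname SourceEstimate-class
#' @export
setMethod("sourceCurrents", "SourceEstimate", function(object) object@currents)
#' @rdname SourceEstimate-class
#' @export
setMethod("epochTimes", "SourceEstimate", function(object) object@times)

#' @rdname EpochSet-class
#' @export
setMethod("dim", "EpochSet", function(x) dim(x@data))

setMethod("show", "SensorLayout", function(object) {
  cat("SensorLayout with", nrow(object@positions), "planar-pair positions,",
      2 * nrow(object@positions), "channels\n")
  cat("  adjacency:", nrow(object@adjacency), "edges (threshold",
      format(object@threshold, digits = 3), ")\n")
  if (length(object@groups)) {
    cat("  groups:", paste(sprintf("%s(%d)", names(object@groups),
                                   lengths(object@groups)), collapse = ", "), "\n")
  }
})

setMethod("show", "ForwardModel", function(object) {
  cat("ForwardModel:", nrow(object@leadfield), "channels x",
      ncol(object@leadfield), "grid points\n")
  cat("  regions:", nlevels(object@regionLabels), "|",
      paste(head(levels(object@regionLabels), 6), collapse = ", "),
      if (nlevels(object@regionLabels) > 6) "..." else "", "\n")
})

setMethod("show", "ContinuousRecording", function(object) {
  cat("ContinuousRecording [subject ", object@subject, "]: ",
      nrow(object@data), " channels x ", ncol(object@data), " samples @ ",
      object@sfreq, " Hz\n", sep = "")
  cat("  triggers:", nrow(object@triggers), "| baseline intervals:",
      nrow(object@baselineIntervals), "\n")
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat("EpochSet: ", d[1], " trials x ", d[2],
      if (object@combined) " positions (combined planar) x " else " channels x ",
      d[3], " samples, t in [", format(min(object@times), digits = 3), ", ",
      format(max(object@times), digits = 3), "] s\n", sep = "")
  if (nlevels(object@conditions) > 0) {
    tb <- table(object@conditions)
    cat("  conditions:", paste(sprintf("%s(%d)", names(tb), tb), collapse = ", "), "\n")
  }
})

setMethod("show", "InverseOperator", function(object) {
  cat("InverseOperator:", nrow(object@matrix), "grid points x",
      ncol(object@matrix), "sensors, lambda =",
      format(object@lambda, digits = 4),
      if (object@pseudoinverse) "(pseudoinverse fallback)" else "", "\n")
})

setMethod("show", "SourceEstimate", function(object) {
  cat("SourceEstimate:", nrow(object@currents), "grid points x",
      ncol(object@currents), "samples\n")
})
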
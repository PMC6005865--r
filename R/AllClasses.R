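## S4 containers for the MEG side of the pipeline.  The behavioral side works
## on plain data.frames (the keystroke event table), statistical results are
## light S3 objects with print methods.

setClassUnion("characterOrNULL", c("character", "NULL"))

#' SensorLayout: planar-gradiometer array geometry
#'
#' Positions of planar gradiometer pairs in a 2D layout plane, the mapping of
#' positions to their two orthogonal channels, the spatial adjacency graph
#' used by cluster statistics, and named sensor groups used by the synthetic
#' generator to target effects.
#'
#' @slot positions numeric matrix, one row per pair position (columns x, y);
#'   rownames are position names.
#' @slot pairMap data.frame with columns \code{position}, \code{hChannel},
#'   \code{vChannel}.
#' @slot adjacency two-column integer matrix of position index pairs
#'   (i < j) whose distance is within the threshold.
#' @slot threshold numeric distance threshold that defined the adjacency.
#' @slot groups named list of integer vectors (position indices).
#' @exportClass SensorLayout
setClass("SensorLayout",
  representation(
    positions = "matrix",
    pairMap = "data.frame",
    adjacency = "matrix",
    threshold = "numeric",
    groups = "list"
  )
)

setValidity("SensorLayout", function(object) {
  msg <- character()
  p <- object@positions
  if (ncol(p) != 2) msg <- c(msg, "positions must have two columns (x, y)")
  if (nrow(p) >= 2) {
    d <- as.matrix(dist(p))
    diag(d) <- Inf
    if (any(d < 1e-9)) msg <- c(msg, "coincident sensor positions")
  }
  pm <- object@pairMap
  need <- c("position", "hChannel", "vChannel")
  if (!all(need %in% names(pm))) {
    msg <- c(msg, "pairMap must have columns position, hChannel, vChannel")
  } else if (nrow(pm) != nrow(p)) {
    msg <- c(msg, "pairMap must have one row per position")
  }
  adj <- object@adjacency
  if (nrow(adj) > 0) {
    if (ncol(adj) != 2) msg <- c(msg, "adjacency must be a two-column matrix")
    else {
      if (any(adj[, 1] == adj[, 2])) msg <- c(msg, "adjacency must be irreflexive")
      if (any(adj < 1) || any(adj > nrow(p))) msg <- c(msg, "adjacency index out of range")
    }
  }
  if (length(msg)) msg else TRUE
})

#' ForwardModel: toy leadfield with a region partition
#'
#' Linear forward operator mapping source currents at grid points to sensor
#' measurements, with 3D grid coordinates, a partition of the grid into named
#' regions, and a grid adjacency graph (used to judge localization accuracy).
#'
#' @slot leadfield numeric matrix, sensors (channels) x grid points; rownames
#'   are channel names.
#' @slot gridCoords numeric matrix, grid points x 3.
#' @slot regionLabels factor of length n grid points.
#' @slot gridAdjacency two-column integer matrix of neighboring grid points.
#' @exportClass ForwardModel
setClass("ForwardModel",
  representation(
    leadfield = "matrix",
    gridCoords = "matrix",
    regionLabels = "factor",
    gridAdjacency = "matrix"
  )
)

setValidity("ForwardModel", function(object) {
  msg <- character()
  L <- object@leadfield
  if (!all(is.finite(L))) msg <- c(msg, "leadfield must be finite")
  if (any(colSums(abs(L)) == 0)) {
    msg <- c(msg, "leadfield has an all-zero column (invisible grid point)")
  }
  if (nrow(object@gridCoords) != ncol(L)) {
    msg <- c(msg, "gridCoords rows must match leadfield columns")
  }
  if (ncol(object@gridCoords) != 3) msg <- c(msg, "gridCoords must be 3D")
  if (length(object@regionLabels) != ncol(L)) {
    msg <- c(msg, "regionLabels must label every grid point exactly once")
  }
  if (any(is.na(object@regionLabels))) msg <- c(msg, "regionLabels must not contain NA")
  if (length(msg)) msg else TRUE
})

#' ContinuousRecording: multi-sensor continuous signal with triggers
#'
#' One subject's continuous multi-channel recording.  Triggers mark keystroke
#' events at keystroke time plus the MIDI trigger delay and carry the event
#' annotations needed downstream (condition, error flag, covariates).
#'
#' @slot data numeric matrix, channels x samples; rownames are channel names.
#' @slot sfreq sampling rate in Hz.
#' @slot triggers data.frame with at least \code{time_ms}, \code{feedback},
#'   \code{position_class}, \code{is_error}, \code{velocity},
#'   \code{preceding_ioi}.
#' @slot baselineIntervals two-column matrix of [start_ms, end_ms) silent
#'   pre-trial intervals (no performance), for noise-covariance estimation.
#' @slot subject subject identifier.
#' @exportClass ContinuousRecording
setClass("ContinuousRecording",
  representation(
    data = "matrix",
    sfreq = "numeric",
    triggers = "data.frame",
    baselineIntervals = "matrix",
    subject = "character"
  )
)

setValidity("ContinuousRecording", function(object) {
  msg <- character()
  if (length(object@sfreq) != 1 || object@sfreq <= 0) msg <- c(msg, "sfreq must be a positive scalar")
  if (is.null(rownames(object@data))) msg <- c(msg, "data must have channel rownames")
  tr <- object@triggers
  need <- c("time_ms", "feedback", "position_class", "is_error")
  if (!all(need %in% names(tr))) {
    msg <- c(msg, paste("triggers must include:", paste(need, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' EpochSet: trials x channels x time evoked-field array
#'
#' Epoched (or trial-averaged) sensor data time-locked to the keystroke
#' (t = 0 after MIDI-trigger latency correction), with condition labels and
#' per-trial covariates.
#'
#' @slot data numeric array, trials x channels x time samples.
#' @slot times numeric vector of sample times in seconds relative to the
#'   keystroke; uniform spacing.
#' @slot sfreq sampling rate in Hz.
#' @slot conditions factor of length n trials (e.g. "AF-Bo", "NF-In").
#' @slot covariates data.frame with one row per trial.
#' @slot subject subject identifier (may be NULL for synthetic sets).
#' @slot combined logical; TRUE once planar pairs have been combined into
#'   non-negative per-position magnitudes.
#' @exportClass EpochSet
setClass("EpochSet",
  representation(
    data = "array",
    times = "numeric",
    sfreq = "numeric",
    conditions = "factor",
    covariates = "data.frame",
    subject = "characterOrNULL",
    combined = "logical"
  )
)

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3) msg <- c(msg, "data must be a 3D array (trials x channels x time)")
  else {
    if (length(object@times) != d[3]) msg <- c(msg, "times length must match the time dimension")
    if (length(object@conditions) != d[1]) msg <- c(msg, "conditions length must match the trial count")
    if (nrow(object@covariates) > 0 && nrow(object@covariates) != d[1]) {
      msg <- c(msg, "covariates must have one row per trial")
    }
  }
  if (length(object@times) >= 2) {
    dt <- diff(object@times)
    if (any(dt <= 0) || diff(range(dt)) > 1e-6 * mean(dt)) {
      msg <- c(msg, "times must be strictly increasing and uniform")
    }
  }
  if (length(msg)) msg else TRUE
})

#' InverseOperator: L2 minimum-norm inverse mapping
#'
#' @slot matrix numeric matrix, grid points x sensors.
#' @slot lambda regularization parameter (scalar, >= 0).
#' @slot noiseCov sensor noise covariance used in the construction.
#' @slot pseudoinverse logical; TRUE when the unregularized system was
#'   rank-deficient and the pseudoinverse fallback was used.
#' @exportClass InverseOperator
setClass("InverseOperator",
  representation(
    matrix = "matrix",
    lambda = "numeric",
    noiseCov = "matrix",
    pseudoinverse = "logical"
  )
)

setValidity("InverseOperator", function(object) {
  msg <- character()
  if (length(object@lambda) != 1 || object@lambda < 0) msg <- c(msg, "lambda must be a scalar >= 0")
  C <- object@noiseCov
  if (nrow(C) != ncol(C)) msg <- c(msg, "noiseCov must be square")
  else if (max(abs(C - t(C))) > 1e-8 * max(1, max(abs(C)))) msg <- c(msg, "noiseCov must be symmetric")
  if (ncol(object@matrix) != nrow(C)) msg <- c(msg, "operator columns must match noiseCov dimension")
  if (length(msg)) msg else TRUE
})

#' SourceEstimate: distributed source currents over time
#'
#' @slot currents numeric matrix, grid points x time samples (nominal nAm).
#' @slot times numeric vector of sample times in seconds.
#' @exportClass SourceEstimate
setClass("SourceEstimate",
  representation(
    currents = "matrix",
    times = "numeric"
  )
)

setValidity("SourceEstimate", function(object) {
  if (ncol(object@currents) != length(object@times)) {
    "currents columns must match times length"
  } else TRUE
})
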
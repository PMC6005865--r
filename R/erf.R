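#' Zero-phase band-pass filter
#'
#' Band-pass filters each channel with a Butterworth filter applied forward
#' and backward (\code{signal::filtfilt}), giving zero phase distortion and
#' removing DC.  The default 1-100 Hz band reproduces the standard evoked-
#' field preprocessing band.
#'
#' @param x a \code{\link{ContinuousRecording-class}} or a channels x
#'   samples numeric matrix.
#' @param low,high band edges in Hz; requires 0 < low < high < sfreq/2.
#' @param sfreq sampling rate in Hz (taken from the recording when \code{x}
#'   is a \code{ContinuousRecording}).
#' @param order Butterworth section order (effective order doubles with the
#'   forward-backward pass).
#' @return object of the same type as \code{x}, filtered.
#' @export
bandpassFilter <- function(x, low = 1, high = 100, sfreq = NULL, order = 4) {
  if (is(x, "ContinuousRecording")) {
    out <- x
    out@data <- bandpassFilter(recordingData(x), low, high, samplingRate(x),
                               order)
    return(out)
  }
  if (is.null(sfreq)) stop("sfreq is required for matrix input")
  if (!is.numeric(low) || !is.numeric(high) || low <= 0 || high <= low ||
      high >= sfreq / 2) {
    stop("invalid band edges: need 0 < low < high < sfreq/2")
  }
  bf <- signal::butter(order, c(low, high) / (sfreq / 2), type = "pass")
  filt <- t(apply(x, 1, function(ch) signal::filtfilt(bf, ch)))
  dimnames(filt) <- dimnames(x)
  filt
}

#' Epoch a continuous recording around keystrokes
#'
#' Cuts epochs time-locked to the keystroke: each trigger time is shifted
#' back by the MIDI-trigger latency so that t = 0 is the keystroke itself.
#' Triggers whose window does not fit inside the recording are dropped (a
#' message reports the count).
#'
#' @param recording a \code{\link{ContinuousRecording-class}}.
#' @param latencyCorrection trigger-to-keystroke delay in ms to subtract.
#' @param window epoch window in seconds relative to the keystroke.
#' @param select optional logical/integer index into the trigger table
#'   choosing which events to epoch (e.g. the output of
#'   \code{\link{selectMatchedControls}}).
#' @return an \code{\link{EpochSet-class}}; conditions are
#'   "feedback-position" labels, covariates carry preceding IOI and
#'   velocity.
#' @export
epochRecording <- function(recording, latencyCorrection = 22.5,
                           window = c(-1, 1), select = NULL) {
  stopifnot(is(recording, "ContinuousRecording"))
  sfreq <- samplingRate(recording)
  dat <- recordingData(recording)
  trg <- triggers(recording)
  if (!is.null(select)) trg <- trg[select, , drop = FALSE]
  if (!nrow(trg)) stop("no triggers to epoch")
  t0 <- trg$time_ms - latencyCorrection
  s0 <- round(t0 / 1000 * sfreq) + 1L
  o1 <- round(window[1] * sfreq)
  o2 <- round(window[2] * sfreq)
  ok <- (s0 + o1) >= 1L & (s0 + o2) <= ncol(dat)
  if (!any(ok)) stop("no valid triggers: all windows fall outside the recording")
  if (any(!ok)) message(sum(!ok), " trigger(s) dropped (incomplete window)")
  trg <- trg[ok, , drop = FALSE]
  s0 <- s0[ok]
  offs <- o1:o2
  nT <- length(offs)
  arr <- array(0, c(length(s0), nrow(dat), nT),
               dimnames = list(NULL, rownames(dat), NULL))
  for (i in seq_along(s0)) arr[i, , ] <- dat[, s0[i] + offs]
  cond <- factor(.conditionLabel(trg$feedback, trg$position_class),
                 levels = .CONDITIONS)
  new("EpochSet", data = arr, times = offs / sfreq, sfreq = sfreq,
      conditions = cond,
      covariates = data.frame(preceding_ioi = trg$preceding_ioi,
                              velocity = trg$velocity,
                              is_error = trg$is_error,
                              block = trg$block, trial = trg$trial,
                              keystroke = trg$keystroke),
      subject = recording@subject, combined = FALSE)
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the pre-keystroke
#' baseline window (default -200 to -100 ms).
#'
#' @param epochs an \code{\link{EpochSet-class}}.
#' @param window baseline window in seconds; must lie inside the epoch.
#' @return the corrected \code{EpochSet}.
#' @export
baselineCorrect <- function(epochs, window = c(-0.2, -0.1)) {
  stopifnot(is(epochs, "EpochSet"))
  idx <- .windowIndex(epochs@times, window)
  if (!length(idx) || window[1] < min(epochs@times) - 1e-9 ||
      window[2] > max(epochs@times) + 1e-9) {
    stop("baseline window must lie fully inside the epoch")
  }
  bl <- rowMeans(epochs@data[, , idx, drop = FALSE], dims = 2)
  epochs@data <- epochs@data - array(bl, dim(epochs@data))
  epochs
}

#' Combine planar gradiometer pairs
#'
#' Combines the horizontal and vertical channel at each sensor position into
#' a single non-negative magnitude, \code{sqrt(h^2 + v^2)} (scheme "norm",
#' the standard combined-planar representation) or
#' \code{sqrt((h^2 + v^2)/2)} (scheme "rms").  Because the combination is
#' nonlinear, condition averaging is done first in the pipeline and the
#' combination applied to the averaged fields.
#'
#' @param x an \code{\link{EpochSet-class}} (combined per trial) or a
#'   channels x time matrix (e.g. an averaged ERF).
#' @param layout the \code{\link{SensorLayout-class}} supplying the pair map.
#' @param scheme "norm" (default) or "rms".
#' @return same type as \code{x}, with one row/channel per pair position.
#' @examples
#' lay <- generateSensorLayout(4)
#' m <- matrix(c(3, 4), 2, 5, dimnames = list(c("P01_h", "P01_v"), NULL))
#' combinePlanar(m, lay)  # constant 5
#' @export
combinePlanar <- function(x, layout, scheme = c("norm", "rms")) {
  scheme <- match.arg(scheme)
  pm <- pairMap(layout)
  if (is(x, "EpochSet")) {
    if (x@combined) stop("epochs are already planar-combined")
    d <- dim(x@data)
    chans <- dimnames(x@data)[[2]]
    hi <- .pairIndex(pm$hChannel, chans)
    vi <- .pairIndex(pm$vChannel, chans)
    comb <- x@data[, hi, , drop = FALSE]^2 + x@data[, vi, , drop = FALSE]^2
    if (scheme == "rms") comb <- comb / 2
    comb <- sqrt(comb)
    dimnames(comb)[[2]] <- pm$position
    x@data <- comb
    x@combined <- TRUE
    return(x)
  }
  chans <- rownames(x)
  hi <- .pairIndex(pm$hChannel, chans)
  vi <- .pairIndex(pm$vChannel, chans)
  comb <- x[hi, , drop = FALSE]^2 + x[vi, , drop = FALSE]^2
  if (scheme == "rms") comb <- comb / 2
  comb <- sqrt(comb)
  rownames(comb) <- pm$position
  comb
}

.pairIndex <- function(wanted, chans) {
  i <- match(wanted, chans)
  if (anyNA(i)) {
    stop("unpaired sensor(s): ", paste(wanted[is.na(i)], collapse = ", "))
  }
  i
}

#' Condition-average event-related fields
#'
#' Trial-wise mean per condition.  Errors if a requested condition has no
#' trials; the trial counts per condition are attached as an attribute.
#'
#' @param epochs an \code{\link{EpochSet-class}}.
#' @param which conditions to average (default: all levels present).
#' @return named list of channels x time matrices, one per condition, with
#'   attribute \code{counts}.
#' @export
conditionAverage <- function(epochs, which = NULL) {
  stopifnot(is(epochs, "EpochSet"))
  cond <- droplevels(epochs@conditions)
  if (is.null(which)) which <- levels(cond)
  out <- lapply(which, function(cc) {
    sel <- which(cond == cc)
    if (!length(sel)) stop("empty condition: ", cc)
    colMeans(epochs@data[sel, , , drop = FALSE], dims = 1)
  })
  names(out) <- which
  attr(out, "counts") <- vapply(which, function(cc) sum(cond == cc), integer(1))
  attr(out, "times") <- epochs@times
  out
}

#' Select timing- and velocity-matched NF control events
#'
#' For each positional class, selects from the pool of normal-feedback (NF)
#' keystrokes a control set of the same size as the altered-feedback (AF)
#' target set, matched on preceding inter-onset interval and keystroke
#' velocity.  NF keystrokes at +1 or +2 after an AF event are excluded from
#' the pool, as are error keystrokes (epochs are time-locked to correctly
#' played keystrokes).  Matching is greedy nearest-neighbour without
#' replacement on z-scored (preceding IOI, velocity) Euclidean distance;
#' a warning is issued when a selected set's covariate mean drifts more
#' than 0.25 pooled standard deviations from the AF mean.
#'
#' @param trg a trigger table (see \code{\link{ContinuousRecording-class}});
#'   rows must be in within-trial keystroke order.
#' @return list with \code{af} (row indices of eligible AF target events)
#'   and \code{nf} (row indices of the selected NF controls), both named by
#'   class, plus a \code{balance} data.frame.
#' @export
selectMatchedControls <- function(trg) {
  need <- c("feedback", "position_class", "is_error", "velocity",
            "preceding_ioi")
  miss <- setdiff(need, names(trg))
  if (length(miss)) stop("trigger table lacks columns: ",
                         paste(miss, collapse = ", "))
  n <- nrow(trg)
  postAf <- if ("gt_post_af" %in% names(trg)) {
    trg$gt_post_af %in% c(1L, 2L)
  } else {
    flag <- logical(n)
    key <- interaction(trg$block, trg$trial, drop = TRUE)
    for (idx in split(seq_len(n), key)) {
      af <- which(trg$feedback[idx] == "AF")
      for (k in c(1L, 2L)) {
        p <- af + k
        flag[idx[p[p <= length(idx)]]] <- TRUE
      }
    }
    flag
  }
  ok <- !is.na(trg$preceding_ioi) & !trg$is_error
  af <- list(); nf <- list(); bal <- list()
  for (cl in c("Bo", "In")) {
    tIdx <- which(ok & trg$feedback == "AF" & trg$position_class == cl)
    pIdx <- which(ok & trg$feedback == "NF" & trg$position_class == cl & !postAf)
    if (!length(tIdx)) next
    if (length(pIdx) < length(tIdx)) {
      stop("NF pool exhausted for class ", cl, " (", length(pIdx),
           " < ", length(tIdx), ")")
    }
    covAll <- cbind(trg$preceding_ioi[c(tIdx, pIdx)],
                    trg$velocity[c(tIdx, pIdx)])
    mu <- colMeans(covAll)
    sdv <- pmax(apply(covAll, 2, sd), 1e-12)
    zt <- sweep(sweep(cbind(trg$preceding_ioi[tIdx], trg$velocity[tIdx]),
                      2, mu), 2, sdv, "/")
    zp <- sweep(sweep(cbind(trg$preceding_ioi[pIdx], trg$velocity[pIdx]),
                      2, mu), 2, sdv, "/")
    sel <- .greedyMatch(zt, zp)
    af[[cl]] <- tIdx
    nf[[cl]] <- pIdx[sel]
    drift <- abs(colMeans(zp[sel, , drop = FALSE]) - colMeans(zt))
    if (any(drift > 0.25)) {
      warning("matched NF controls for class ", cl,
              " drift > 0.25 pooled sd from the AF covariate means")
    }
    bal[[cl]] <- data.frame(class = cl,
                            d_ioi_sd = drift[1], d_velocity_sd = drift[2],
                            n = length(tIdx))
  }
  if (!length(af)) stop("no eligible AF target events")
  list(af = af, nf = nf, balance = do.call(rbind, bal))
}

## greedy nearest-neighbour assignment without replacement;
## targets processed in given order
.greedyMatch <- function(zt, zp) {
  avail <- rep(TRUE, nrow(zp))
  sel <- integer(nrow(zt))
  for (i in seq_len(nrow(zt))) {
    d2 <- (zp[, 1] - zt[i, 1])^2 + (zp[, 2] - zt[i, 2])^2
    d2[!avail] <- Inf
    j <- which.min(d2)
    sel[i] <- j
    avail[j] <- FALSE
  }
  sel
}
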
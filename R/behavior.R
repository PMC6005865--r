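#' Inter-onset intervals
#'
#' Adds an \code{ioi} column (ms): time between consecutive keystrokes
#' within each trial.  The first keystroke of a trial has no defined
#' interval and is flagged \code{NA} (excluded from all means).  Intervals
#' are never computed across trial borders.
#'
#' @param events keystroke event table.
#' @return \code{events} with an \code{ioi} column appended.
#' @examples
#' ev <- data.frame(subject = 1, block = 1, trial = 1, keystroke = 1:4,
#'                  onset_ms = c(0, 300, 600, 900))
#' computeIOI(ev)$ioi
#' @export
computeIOI <- function(events) {
  key <- .trialKey(events)
  bad <- vapply(split(events$onset_ms, key),
                function(on) any(diff(on) <= 0), logical(1))
  if (any(bad)) {
    stop("non-monotonic onsets within trial(s): ",
         paste(names(bad)[bad], collapse = ", "))
  }
  events$ioi <- ave(events$onset_ms, key, FUN = function(x) c(NA, diff(x)))
  events
}

#' Per-trial timing summaries: mean IOI and cvIOI
#'
#' The coefficient of variation of the inter-onset interval (cvIOI =
#' sd(IOI)/mean(IOI)) and the mean IOI, per subject x block x trial.
#'
#' @param events keystroke event table.
#' @return data.frame with columns \code{subject}, \code{block},
#'   \code{trial}, \code{n_ioi}, \code{mean_ioi}, \code{cv_ioi}.
#' @export
computeCvIOI <- function(events) {
  if (is.null(events$ioi)) events <- computeIOI(events)
  keys <- unique(events[, c("subject", "block", "trial")])
  rownames(keys) <- NULL
  spl <- split(events$ioi,
               interaction(events$subject, events$block, events$trial,
                           drop = TRUE, sep = "/"))
  ord <- match(paste(keys$subject, keys$block, keys$trial, sep = "/"), names(spl))
  stats <- t(vapply(spl[ord], function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) return(c(length(x), mean(x), NA_real_))
    c(length(x), mean(x), sd(x) / mean(x))
  }, numeric(3)))
  keys$n_ioi <- as.integer(stats[, 1])
  keys$mean_ioi <- stats[, 2]
  keys$cv_ioi <- stats[, 3]
  keys
}

#' Derive pitch errors from the played stream
#'
#' Flags a keystroke as an error when the played pitch deviates from the
#' pattern pitch expected at its cyclic position.  The aligner assumes
#' substitution errors (the stream stays in phase with the pattern cycle),
#' resynchronizing at the next pattern match; this matches how the
#' synthetic generator corrupts streams and yields the generator's ground
#' truth exactly for substitution-only corruption.
#'
#' @param events keystroke event table (uses \code{pitch_played} and
#'   \code{block} to look up the pattern).
#' @param patterns list of pitch patterns indexed by block.
#' @return \code{events} with a recomputed logical \code{is_error} column.
#' @export
detectErrors <- function(events, patterns) {
  if (any(!events$block %in% seq_along(patterns))) {
    stop("unknown pattern id in 'block' column")
  }
  err <- logical(nrow(events))
  for (key in split(seq_len(nrow(events)), .trialKey(events))) {
    idx <- key[order(events$keystroke[key])]
    pat <- patterns[[events$block[idx[1]]]]
    pos <- rep_len(seq_along(pat), length(idx))
    err[idx] <- events$pitch_played[idx] != pat[pos]
  }
  events$is_error <- err
  events
}

#' Windowed error rate after feedback events
#'
#' For every feedback event (each AF keystroke and, scored symmetrically,
#' each NF keystroke), counts whether at least one pitch error occurs within
#' the next \code{horizon} keystrokes of the same trial.  Events followed by
#' an AF event within that window are excluded from both numerator and
#' denominator, because a later alteration could itself have induced the
#' error.  Windows are clipped at the trial end (a late event with fewer
#' than \code{horizon} following keystrokes stays eligible over the
#' truncated window).  Rates are aggregated per subject and condition
#' (feedback x position class).
#'
#' @param events keystroke event table with an \code{is_error} column.
#' @param horizon window length in keystrokes (>= 1).
#' @return data.frame with \code{subject}, \code{feedback},
#'   \code{position_class}, \code{n_events} (eligible events),
#'   \code{n_induced}, \code{rate} (NA with a warning when no event is
#'   eligible).
#' @export
computeErrorRate <- function(events, horizon = 5) {
  .assertScalar(horizon, "horizon", lower = 1)
  horizon <- as.integer(horizon)
  sc <- .scoreWindows(events, horizon)
  agg <- aggregate(cbind(n_events = sc$eligible, n_induced = sc$eligible & sc$induced),
                   by = list(subject = events$subject, feedback = events$feedback,
                             position_class = events$position_class),
                   FUN = sum)
  agg$rate <- ifelse(agg$n_events > 0, agg$n_induced / agg$n_events, NA_real_)
  if (any(agg$n_events == 0)) {
    warning("empty denominator for some subject x condition cells; rate set to NA")
  }
  agg[order(agg$subject, agg$feedback, agg$position_class), ]
}

## Per-event forward-window scan: for each keystroke, whether an error and
## whether an AF event occurs in the next `horizon` keystrokes of the trial.
.scoreWindows <- function(events, horizon) {
  n <- nrow(events)
  induced <- logical(n)
  afAhead <- logical(n)
  for (idx in split(seq_len(n), .trialKey(events))) {
    idx <- idx[order(events$keystroke[idx])]
    m <- length(idx)
    errC <- cumsum(events$is_error[idx])
    afC <- cumsum(events$feedback[idx] == "AF")
    i <- seq_len(m)
    hi <- pmin(i + horizon, m)
    induced[idx] <- (errC[hi] - errC[i]) > 0
    afAhead[idx] <- (afC[hi] - afC[i]) > 0
  }
  list(induced = induced, eligible = !afAhead)
}

#' Post-feedback timing change at the subsequent keystroke
#'
#' For each feedback event, the difference in inter-onset interval between
#' the first subsequent keystroke and the event itself (delta IOI at +1, in
#' ms), averaged per subject and condition.  Events without a defined own
#' interval (first keystroke of a trial) or without a +1 keystroke in the
#' same trial are excluded.  NF keystrokes at +1 or +2 after an AF event
#' are not scored as NF events, so that the configured post-AF slowing
#' cannot leak into the NF reference.
#'
#' @param events keystroke event table.
#' @return data.frame with \code{subject}, \code{feedback},
#'   \code{position_class}, \code{n_events}, \code{mean_dioi}.
#' @export
computePostFeedbackChange <- function(events) {
  if (is.null(events$ioi)) events <- computeIOI(events)
  n <- nrow(events)
  dioi <- rep(NA_real_, n)
  excl <- logical(n)
  for (idx in split(seq_len(n), .trialKey(events))) {
    idx <- idx[order(events$keystroke[idx])]
    m <- length(idx)
    ioi <- events$ioi[idx]
    d <- c(ioi[-1], NA) - ioi          # IOI(+1) - IOI(event)
    d[m] <- NA                         # no +1 keystroke
    dioi[idx] <- d
    af <- events$feedback[idx] == "AF"
    post <- which(af)
    for (k in c(1L, 2L)) {
      p <- post + k
      excl[idx[p[p <= m]]] <- TRUE
    }
  }
  excl <- excl & events$feedback == "NF"
  ok <- !is.na(dioi) & !excl
  agg <- aggregate(list(mean_dioi = dioi[ok]),
                   by = list(subject = events$subject[ok],
                             feedback = events$feedback[ok],
                             position_class = events$position_class[ok]),
                   FUN = mean)
  cnt <- aggregate(list(n_events = rep(1L, sum(ok))),
                   by = list(subject = events$subject[ok],
                             feedback = events$feedback[ok],
                             position_class = events$position_class[ok]),
                   FUN = sum)
  out <- merge(agg, cnt)
  out[order(out$subject, out$feedback, out$position_class),
      c("subject", "feedback", "position_class", "n_events", "mean_dioi")]
}

#' Learning trajectories on perturbation-free trials
#'
#' Restricted to AF-free (purely NF) trials, which are the cleanest probe of
#' training effects: per-subject per-trial tempo (mean IOI) and cvIOI
#' trajectories, the first-vs-last AF-free-trial cvIOI pairs, and
#' first-vs-second experiment-half mean-IOI pairs, ready for paired
#' permutation testing.
#'
#' @param events keystroke event table.
#' @param afFreeTrials within-block indices of the perturbation-free trials.
#' @return list with \code{trajectory} (subject x block x trial summaries),
#'   \code{cvPairs} (subject, first, last) and \code{halfPairs} (subject,
#'   firstHalf, secondHalf mean IOI).
#' @export
learningCurves <- function(events, afFreeTrials = c(1, 6, 10)) {
  nf <- events[events$trial %in% afFreeTrials, , drop = FALSE]
  if (!nrow(nf)) stop("no AF-free trials present")
  traj <- computeCvIOI(nf)
  tmin <- min(traj$trial); tmax <- max(traj$trial)
  if (tmin == tmax) stop("need at least two AF-free trials per block for learning curves")
  firstT <- traj[traj$trial == tmin, ]
  lastT <- traj[traj$trial == tmax, ]
  cvPairs <- data.frame(
    subject = sort(unique(traj$subject)),
    first = tapply(firstT$cv_ioi, firstT$subject, mean, na.rm = TRUE),
    last = tapply(lastT$cv_ioi, lastT$subject, mean, na.rm = TRUE)
  )
  ## experiment halves by block order
  blocks <- sort(unique(traj$block))
  half1 <- blocks[seq_len(ceiling(length(blocks) / 2))]
  h <- ifelse(traj$block %in% half1, "firstHalf", "secondHalf")
  mh <- tapply(traj$mean_ioi, list(traj$subject, h), mean, na.rm = TRUE)
  halfPairs <- data.frame(subject = as.integer(rownames(mh)),
                          firstHalf = mh[, "firstHalf"],
                          secondHalf = if ("secondHalf" %in% colnames(mh))
                            mh[, "secondHalf"] else NA_real_)
  rownames(cvPairs) <- rownames(halfPairs) <- NULL
  list(trajectory = traj, cvPairs = cvPairs, halfPairs = halfPairs)
}

#' Per-subject condition summary
#'
#' Joins the windowed error rates and the post-feedback timing change into
#' one table per subject x condition, plus the per-trial timing summaries.
#'
#' @param events keystroke event table.
#' @param horizon error-rate window in keystrokes.
#' @return list with \code{conditions} (subject, feedback, position_class,
#'   error rate and delta-IOI columns) and \code{trials} (per-trial mean IOI
#'   and cvIOI).
#' @export
conditionSummary <- function(events, horizon = 5) {
  er <- computeErrorRate(events, horizon = horizon)
  di <- computePostFeedbackChange(events)
  cond <- merge(er, di,
                by = c("subject", "feedback", "position_class"),
                suffixes = c("_err", "_dioi"), all = TRUE)
  list(conditions = cond, trials = computeCvIOI(events))
}

#' Reshape a per-subject condition metric into 2x2 factorial cells
#'
#' @param tab data.frame with \code{subject}, \code{feedback},
#'   \code{position_class} and the metric column \code{value}.
#' @param value name of the metric column.
#' @return matrix subjects x 4 with columns \code{NF-Bo}, \code{NF-In},
#'   \code{AF-Bo}, \code{AF-In} (feedback = factor A, position = factor B).
#' @export
conditionCells <- function(tab, value) {
  if (!value %in% names(tab)) stop("no column '", value, "'")
  lab <- .conditionLabel(tab$feedback, tab$position_class)
  subj <- sort(unique(tab$subject))
  cells <- matrix(NA_real_, length(subj), 4,
                  dimnames = list(subj, .CONDITIONS))
  cells[cbind(match(tab$subject, subj), match(lab, .CONDITIONS))] <- tab[[value]]
  cells
}
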
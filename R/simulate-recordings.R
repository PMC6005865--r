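#' Generate continuous multi-sensor recordings with triggers
#'
#' Builds one continuous recording per subject from a keystroke event table.
#' Trials are laid out sequentially, each preceded by a silent inter-trial
#' gap (the no-performance intervals later used for noise-covariance
#' estimation).  Sensor noise is AR(1) plus white innovations; every
#' keystroke matching a planted effect (see \code{\link{erfEffect}})
#' deposits a half-sine template on the horizontal channels of the target
#' sensor group at the configured post-keystroke latency.  Triggers are
#' recorded at keystroke time plus the MIDI trigger delay.
#'
#' @param events keystroke event table from \code{\link{generatePerformance}}.
#' @param layout a \code{\link{SensorLayout-class}}.
#' @param config the \code{\link{simulationConfig}} used to generate
#'   \code{events}; supplies the noise model, sampling rate, trigger delay
#'   and planted effects.
#' @param subjects subjects to generate (default: all in \code{events}).
#' @return named list of \code{\link{ContinuousRecording-class}} objects.
#' @export
generateRecordings <- function(events, layout, config, subjects = NULL) {
  stopifnot(inherits(config, "SimulationConfig"), is(layout, "SensorLayout"))
  validateEventTable(events)
  for (e in config$erfEffects) {
    .validateErfEffect(e)
    if (!e$group %in% names(sensorGroups(layout))) {
      stop("unknown sensor group in erf effect: ", e$group)
    }
  }
  if (is.null(subjects)) subjects <- sort(unique(events$subject))
  res <- lapply(subjects, function(s) {
    .recordingForSubject(events[events$subject == s, , drop = FALSE],
                         layout, config, s)
  })
  names(res) <- sprintf("S%02d", subjects)
  res
}

.recordingForSubject <- function(ev, layout, config, subj) {
  sfreq <- config$sfreq
  gapMs <- config$interTrialGap * 1000
  chans <- channelNames(layout)
  nCh <- length(chans)
  ord <- order(ev$block, ev$trial, ev$keystroke)
  ev <- ev[ord, , drop = FALSE]
  trialIds <- unique(ev[, c("block", "trial")])

  ## timeline: [gap][trial 1][gap][trial 2]...; epochs need 1 s margins
  cursor <- 0
  starts <- numeric(nrow(trialIds))
  basel <- matrix(0, nrow(trialIds), 2,
                  dimnames = list(NULL, c("start_ms", "end_ms")))
  absOnset <- numeric(nrow(ev))
  for (i in seq_len(nrow(trialIds))) {
    sel <- ev$block == trialIds$block[i] & ev$trial == trialIds$trial[i]
    basel[i, ] <- c(cursor, cursor + gapMs)
    starts[i] <- cursor + gapMs
    absOnset[sel] <- starts[i] + ev$onset_ms[sel]
    cursor <- starts[i] + max(ev$onset_ms[sel]) + 1100
  }
  nSamp <- ceiling(cursor / 1000 * sfreq) + 1L

  .setSeed(.childSeed(config$seed, 1000L + subj))
  data <- matrix(0, nCh, nSamp, dimnames = list(chans, NULL))
  if (config$noiseSd > 0) {
    for (ch in seq_len(nCh)) {
      innov <- rnorm(nSamp, 0, config$noiseSd)
      data[ch, ] <- as.numeric(
        stats::filter(innov, config$noiseAr, method = "recursive"))
    }
  }

  ## deposit planted condition-specific templates
  pm <- pairMap(layout)
  for (eff in config$erfEffects) {
    match <- rep(TRUE, nrow(ev))
    if (!is.na(eff$feedback)) match <- match & ev$feedback == eff$feedback
    if (!is.na(eff$position)) match <- match & ev$position_class == eff$position
    if (!any(match)) next
    o1 <- round(eff$window[1] * sfreq)
    o2 <- round(eff$window[2] * sfreq)
    len <- o2 - o1
    if (len < 1) next
    bump <- eff$amplitude * sin(pi * (seq_len(len) - 0.5) / len)
    rows <- base::match(pm$hChannel[sensorGroups(layout)[[eff$group]]], chans)
    s0 <- round(absOnset[match] / 1000 * sfreq) + 1L
    for (s in s0) {
      idx <- (s + o1):(s + o2 - 1L)
      ok <- idx >= 1L & idx <= nSamp
      if (!any(ok)) next
      data[rows, idx[ok]] <- data[rows, idx[ok]] +
        rep(bump[ok], each = length(rows))
    }
  }

  trg <- data.frame(
    time_ms = absOnset + config$midiTriggerDelay,
    block = ev$block, trial = ev$trial, keystroke = ev$keystroke,
    feedback = ev$feedback, position_class = ev$position_class,
    seq_position = ev$seq_position, is_error = ev$is_error,
    velocity = ev$velocity,
    preceding_ioi = ave(ev$onset_ms, ev$block, ev$trial,
                        FUN = function(x) c(NA, diff(x))),
    gt_post_af = ev$gt_post_af,
    stringsAsFactors = FALSE
  )
  new("ContinuousRecording", data = data, sfreq = sfreq, triggers = trg,
      baselineIntervals = basel, subject = sprintf("S%02d", subj))
}
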
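#' Simulation configuration
#'
#' Builds a validated configuration for the synthetic-data generator.  The
#' defaults reproduce the study conditions of the altered-feedback piano
#' paradigm: blocks of 15 trials of 23 s continuous playing of short (4-5
#' note) sequences at a metronome-induced 200 bpm tempo, feedback alterations
#' (AF) inserted randomly between every 8th and 10th produced keystroke on
#' all but the perturbation-free trials 1, 6 and 10, AF events landing on
#' boundary (first/last) or within-sequence ordinal positions, and a MIDI
#' trigger delay in the 20-25 ms range.
#'
#' @param nSubjects number of simulated subjects.
#' @param sequencePatterns list of integer vectors (MIDI pitches), each of
#'   length 4 or 5.  One block of \code{trialsPerBlock} trials is generated
#'   per pattern.
#' @param trialsPerBlock trials per sequence block.
#' @param trialDuration trial length in seconds of continuous playing.
#' @param tempo induced tempo in beats per minute; the nominal inter-onset
#'   interval is \code{60000/tempo} ms.
#' @param afSpacing integer interval \code{c(min, max)}: gap in keystrokes
#'   between consecutive AF events.
#' @param afSpacingWeights optional weights over the spacings
#'   \code{afSpacing[1]:afSpacing[2]} (default uniform).
#' @param afFreeTrials within-block trial indices left perturbation-free.
#' @param slowingEffect named numeric \code{c(Bo=, In=)}: ms added to the
#'   inter-onset interval of the keystroke following an AF event of that
#'   positional class (ground-truth post-feedback slowing).
#' @param errorBoost named numeric \code{c(Bo=, In=)}: per-keystroke
#'   increment of the error probability within the 5 keystrokes following an
#'   AF event of that class.
#' @param baselineErrorProb per-keystroke baseline error probability.
#' @param ioiNoiseSd standard deviation (ms) of Gaussian timing noise on each
#'   inter-onset interval.  The default 75 ms yields a coefficient of
#'   variation of about 0.25 at the 300 ms nominal interval, matching the
#'   timing variability typical of non-pianist performers in this paradigm.
#' @param midiTriggerDelay delay (ms) between the keystroke and its recorded
#'   trigger, within the hardware's stated 20-25 ms range; default the
#'   midpoint 22.5 ms.
#' @param erfEffects list of planted evoked-field effects; see
#'   \code{\link{erfEffect}}.
#' @param noiseAr lag-one autoregressive coefficient of the sensor noise.
#' @param noiseSd innovation standard deviation of the sensor noise
#'   (arbitrary field units).
#' @param sfreq recording sampling rate in Hz.
#' @param velocityMean,velocitySd Gaussian keystroke (MIDI) velocity.
#' @param interTrialGap silent gap (s) before each trial; these no-playing
#'   intervals provide the noise-covariance baseline.
#' @param seed integer seed making all generator output reproducible.
#'
#' @return an object of class \code{SimulationConfig} (validated list).
#' @examples
#' cfg <- simulationConfig(nSubjects = 2, seed = 1)
#' ev <- generatePerformance(cfg)
#' head(ev)
#' @export
simulationConfig <- function(nSubjects = 20,
                             sequencePatterns = defaultSequencePatterns(),
                             trialsPerBlock = 15,
                             trialDuration = 23,
                             tempo = 200,
                             afSpacing = c(8, 10),
                             afSpacingWeights = NULL,
                             afFreeTrials = c(1, 6, 10),
                             slowingEffect = c(Bo = 50, In = 0),
                             errorBoost = c(Bo = 0.0030, In = 0.0023),
                             baselineErrorProb = 0.001,
                             ioiNoiseSd = 75,
                             midiTriggerDelay = 22.5,
                             erfEffects = list(),
                             noiseAr = 0.9,
                             noiseSd = 1,
                             sfreq = 1000,
                             velocityMean = 64,
                             velocitySd = 8,
                             interTrialGap = 3,
                             seed = 1L) {
  .assertScalar(nSubjects, "nSubjects", lower = 1)
  .assertScalar(trialsPerBlock, "trialsPerBlock", lower = 1)
  .assertScalar(trialDuration, "trialDuration", lower = .Machine$double.eps)
  .assertScalar(tempo, "tempo", lower = .Machine$double.eps)
  if (!is.list(sequencePatterns) || length(sequencePatterns) == 0) {
    stop("sequencePatterns must be a non-empty list of pitch vectors")
  }
  lens <- lengths(sequencePatterns)
  if (!all(lens %in% c(4L, 5L))) {
    stop("sequence patterns must have length 4 or 5")
  }
  if (length(afSpacing) != 2 || afSpacing[1] < 2 || afSpacing[1] > afSpacing[2] ||
      any(afSpacing != round(afSpacing))) {
    stop("afSpacing must be an integer interval c(min, max) with 2 <= min <= max")
  }
  if (!is.null(afSpacingWeights)) {
    if (length(afSpacingWeights) != afSpacing[2] - afSpacing[1] + 1 ||
        any(afSpacingWeights < 0) || sum(afSpacingWeights) <= 0) {
      stop("afSpacingWeights must be non-negative weights over afSpacing[1]:afSpacing[2]")
    }
  }
  for (nm in c("Bo", "In")) {
    if (!nm %in% names(slowingEffect)) stop("slowingEffect must have names Bo and In")
    if (!nm %in% names(errorBoost)) stop("errorBoost must have names Bo and In")
  }
  .assertScalar(baselineErrorProb, "baselineErrorProb", 0, 1)
  if (any(errorBoost < 0) || any(baselineErrorProb + errorBoost > 1)) {
    stop("error probabilities must stay within [0, 1]")
  }
  .assertScalar(ioiNoiseSd, "ioiNoiseSd", lower = 0)
  .assertScalar(midiTriggerDelay, "midiTriggerDelay", 20, 25)
  .assertScalar(noiseAr, "noiseAr", -0.999, 0.999)
  .assertScalar(noiseSd, "noiseSd", lower = 0)
  .assertScalar(sfreq, "sfreq", lower = 1)
  .assertScalar(interTrialGap, "interTrialGap", lower = 0)
  if (length(erfEffects)) {
    for (e in erfEffects) .validateErfEffect(e)
  }

  cfg <- list(
    nSubjects = as.integer(nSubjects),
    sequencePatterns = lapply(sequencePatterns, as.integer),
    trialsPerBlock = as.integer(trialsPerBlock),
    trialDuration = trialDuration,
    tempo = tempo,
    afSpacing = as.integer(afSpacing),
    afSpacingWeights = afSpacingWeights,
    afFreeTrials = as.integer(afFreeTrials),
    slowingEffect = slowingEffect[c("Bo", "In")],
    errorBoost = errorBoost[c("Bo", "In")],
    baselineErrorProb = baselineErrorProb,
    ioiNoiseSd = ioiNoiseSd,
    midiTriggerDelay = midiTriggerDelay,
    erfEffects = erfEffects,
    noiseAr = noiseAr,
    noiseSd = noiseSd,
    sfreq = sfreq,
    velocityMean = velocityMean,
    velocitySd = velocitySd,
    interTrialGap = interTrialGap,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Default sequence patterns
#'
#' Six 4-5 note pitch patterns (MIDI note numbers on a one-octave keyboard),
#' mirroring the six explicitly taught sequence types of the paradigm.
#' @return list of integer vectors.
#' @export
defaultSequencePatterns <- function() {
  list(
    c(61L, 63L, 66L, 68L),
    c(68L, 66L, 61L, 63L),
    c(63L, 68L, 61L, 66L),
    c(61L, 66L, 63L, 68L, 70L),
    c(70L, 63L, 68L, 61L, 66L),
    c(66L, 61L, 70L, 68L, 63L)
  )
}

#' Planted evoked-field effect
#'
#' Describes one condition-dependent template deposited on a sensor group by
#' \code{\link{generateRecordings}}: every keystroke matching the condition
#' filter adds a half-sine bump of the given amplitude on the horizontal
#' channel of each pair in the group, over the given post-keystroke window.
#'
#' @param feedback "AF", "NF" or NA (match any feedback).
#' @param position "Bo", "In" or NA (match any position class).
#' @param group sensor group name (see \code{\link{generateSensorLayout}}).
#' @param window numeric \code{c(from, to)} in seconds post-keystroke,
#'   within [-1, 1].
#' @param amplitude template peak amplitude (field units); may be negative.
#' @return a list of class \code{erfEffect}.
#' @examples
#' erfEffect(feedback = "AF", group = "temporal", window = c(0.26, 0.37), amplitude = 5)
#' @export
erfEffect <- function(feedback = NA, position = NA, group,
                      window, amplitude) {
  e <- list(feedback = feedback, position = position, group = group,
            window = window, amplitude = amplitude)
  class(e) <- "erfEffect"
  .validateErfEffect(e)
  e
}

.validateErfEffect <- function(e) {
  if (!is.list(e) || !all(c("group", "window", "amplitude") %in% names(e))) {
    stop("each erf effect needs fields group, window, amplitude (see erfEffect())")
  }
  if (length(e$window) != 2 || e$window[1] >= e$window[2]) {
    stop("erf effect window must be c(from, to) with from < to")
  }
  if (e$window[1] < -1 || e$window[2] > 1) {
    stop("erf effect window must lie inside the [-1, 1] s epoch range")
  }
  invisible(e)
}

#' Default planted evoked-field effects
#'
#' The effect set used by the end-to-end pipeline when none is supplied:
#' a feedback effect (AF > NF) over temporal sensors in the 0.26-0.37 s
#' window, and a positional effect (Bo > In, regardless of feedback) over
#' frontal sensors in the 0.15-0.205 s window with a later reversal
#' (Bo < In) over temporal sensors at 0.26-0.315 s.
#'
#' @param amplitude peak template amplitude shared by the effects.
#' @return list of \code{\link{erfEffect}} entries.
#' @export
defaultErfEffects <- function(amplitude = 5) {
  list(
    erfEffect(feedback = "AF", group = "temporal",
              window = c(0.26, 0.37), amplitude = amplitude),
    erfEffect(position = "Bo", group = "frontal",
              window = c(0.15, 0.205), amplitude = amplitude),
    erfEffect(position = "In", group = "temporal",
              window = c(0.26, 0.315), amplitude = amplitude * 0.6)
  )
}

#' @export
print.SimulationConfig <- function(x, ...) {
  cat("SimulationConfig\n")
  cat("  subjects:", x$nSubjects, "| patterns:", length(x$sequencePatterns),
      "| trials/block:", x$trialsPerBlock, "x", x$trialDuration, "s\n")
  cat("  tempo:", x$tempo, "bpm (nominal IOI", 60000 / x$tempo, "ms), timing noise sd",
      x$ioiNoiseSd, "ms\n")
  cat("  AF spacing:", paste(x$afSpacing, collapse = "-"),
      "keystrokes; AF-free trials:", paste(x$afFreeTrials, collapse = ","), "\n")
  cat("  slowing (ms):", paste(names(x$slowingEffect), x$slowingEffect,
                               sep = "=", collapse = " "),
      "| error boost:", paste(names(x$errorBoost), x$errorBoost,
                              sep = "=", collapse = " "),
      "| baseline error:", x$baselineErrorProb, "\n")
  cat("  recording:", x$sfreq, "Hz, AR(1) phi =", x$noiseAr,
      ", trigger delay", x$midiTriggerDelay, "ms, seed", x$seed, "\n")
  invisible(x)
}
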
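#' Generate synthetic keystroke performance streams
#'
#' Simulates per-subject, per-trial keystroke event tables under the
#' altered-feedback paradigm.  Keystrokes fall at the nominal inter-onset
#' interval (60000/tempo ms) plus Gaussian timing noise; on non-AF-free
#' trials, altered-feedback events are placed with gaps drawn from
#' \code{afSpacing} and land alternately on boundary (Bo) and
#' within-sequence (In) ordinal positions (random starting class per trial);
#' the configured slowing is added to the inter-onset interval of the
#' keystroke following each AF event, and pitch errors are injected at the
#' baseline rate, boosted within the five keystrokes following an AF event.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return a \code{data.frame} (keystroke event table) with one row per
#'   keystroke: \code{subject}, \code{block}, \code{trial},
#'   \code{keystroke}, \code{onset_ms} (relative to trial start),
#'   \code{pitch_played}, \code{pitch_heard}, \code{velocity},
#'   \code{seq_position}, \code{position_class} ("Bo"/"In"),
#'   \code{feedback} ("NF"/"AF"), \code{is_error}, plus ground-truth columns
#'   \code{gt_af_spacing}, \code{gt_post_af}, \code{gt_slowing_ms},
#'   \code{gt_error_injected}.
#' @examples
#' ev <- generatePerformance(simulationConfig(nSubjects = 1, seed = 7))
#' table(ev$feedback, ev$position_class)
#' @export
generatePerformance <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  nominal <- 60000 / config$tempo
  nKey <- floor(config$trialDuration * 1000 / nominal)
  if (nKey < 2) stop("trialDuration too short for two keystrokes")
  nBlocks <- length(config$sequencePatterns)
  hasAfTrials <- any(!(seq_len(config$trialsPerBlock) %in% config$afFreeTrials))
  if (hasAfTrials && config$afSpacing[1] > nKey) {
    stop("AF spacing exceeds keystrokes per trial: no AF event could be placed")
  }
  spacings <- config$afSpacing[1]:config$afSpacing[2]
  spWeights <- config$afSpacingWeights
  if (is.null(spWeights)) spWeights <- rep(1, length(spacings))

  .setSeed(.childSeed(config$seed, 1L))
  out <- vector("list", config$nSubjects * nBlocks * config$trialsPerBlock)
  k <- 0L
  for (subj in seq_len(config$nSubjects)) {
    for (blk in seq_len(nBlocks)) {
      pattern <- config$sequencePatterns[[blk]]
      L <- length(pattern)
      posCycle <- rep_len(seq_len(L), nKey)
      cls <- ifelse(posCycle == 1L | posCycle == L, "Bo", "In")
      expected <- pattern[posCycle]
      for (tr in seq_len(config$trialsPerBlock)) {
        k <- k + 1L
        ioi <- c(0, pmax(50, rnorm(nKey - 1L, nominal, config$ioiNoiseSd)))

        af <- logical(nKey)
        afSpacingCol <- rep(NA_real_, nKey)
        if (!(tr %in% config$afFreeTrials)) {
          last <- 0L
          desired <- .sample1(c("Bo", "In"))
          repeat {
            win <- (last + config$afSpacing[1]):(last + config$afSpacing[2])
            win <- win[win <= nKey]
            if (!length(win)) break
            w <- spWeights[win - last - config$afSpacing[1] + 1L]
            cand <- win[cls[win] == desired]
            pick <- if (length(cand)) {
              .sample1(cand, prob = w[cls[win] == desired])
            } else {
              .sample1(win, prob = w)
            }
            af[pick] <- TRUE
            afSpacingCol[pick] <- pick - last
            last <- pick
            desired <- if (cls[pick] == "Bo") "In" else "Bo"
          }
        }

        ## post-feedback slowing on the inter-onset interval at +1
        slow <- rep(0, nKey)
        afIdx <- which(af)
        nxt <- afIdx + 1L
        keep <- nxt <= nKey
        slow[nxt[keep]] <- config$slowingEffect[cls[afIdx[keep]]]
        ioi <- ioi + slow
        onset <- cumsum(ioi)

        ## error injection: boosted within 5 keystrokes after an AF event
        postAf <- rep(0L, nKey)
        boostCls <- rep(NA_character_, nKey)
        for (a in afIdx) {
          if (a + 1L > nKey) next
          rng <- (a + 1L):min(a + 5L, nKey)
          postAf[rng] <- seq_along(rng)
          boostCls[rng] <- cls[a]
        }
        p <- rep(config$baselineErrorProb, nKey)
        inBoost <- !is.na(boostCls)
        p[inBoost] <- p[inBoost] + config$errorBoost[boostCls[inBoost]]
        err <- runif(nKey) < p

        played <- expected
        if (any(err)) {
          played[err] <- expected[err] +
            sample(c(-2L, -1L, 1L, 2L), sum(err), replace = TRUE)
        }
        heard <- played
        if (length(afIdx)) {
          shift <- sample(c(-3L, -2L, 2L, 3L), length(afIdx), replace = TRUE)
          heard[afIdx] <- played[afIdx] + shift
        }

        out[[k]] <- list(
          subject = rep.int(subj, nKey), block = rep.int(blk, nKey),
          trial = rep.int(tr, nKey),
          keystroke = seq_len(nKey), onset_ms = onset,
          pitch_played = played, pitch_heard = heard,
          velocity = rnorm(nKey, config$velocityMean, config$velocitySd),
          seq_position = posCycle, position_class = cls,
          feedback = ifelse(af, "AF", "NF"), is_error = err,
          gt_af_spacing = afSpacingCol, gt_post_af = postAf,
          gt_slowing_ms = as.numeric(slow), gt_error_injected = err
        )
      }
    }
  }
  cols <- names(out[[1]])
  res <- lapply(cols, function(cn) unlist(lapply(out, `[[`, cn),
                                          use.names = FALSE))
  names(res) <- cols
  res <- as.data.frame(res, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Validate a keystroke event table
#'
#' Checks the column contract and the structural invariants of a performance
#' event table: onset times strictly increasing within each trial, and
#' boundary labels consistent with the sequence position.
#'
#' @param events a keystroke event table.
#' @param patternLengths optional named lengths per block to check the
#'   Bo/position consistency against.
#' @return the table, invisibly; errors describe the offending trial.
#' @export
validateEventTable <- function(events, patternLengths = NULL) {
  need <- c("subject", "block", "trial", "keystroke", "onset_ms",
            "pitch_played", "pitch_heard", "velocity", "seq_position",
            "position_class", "feedback", "is_error")
  miss <- setdiff(need, names(events))
  if (length(miss)) {
    stop("event table is missing columns: ", paste(miss, collapse = ", "))
  }
  if (!all(events$position_class %in% c("Bo", "In"))) {
    stop("position_class must be 'Bo' or 'In'")
  }
  if (!all(events$feedback %in% c("NF", "AF"))) {
    stop("feedback must be 'NF' or 'AF'")
  }
  bad <- vapply(split(events$onset_ms, .trialKey(events)),
                function(on) any(diff(on) <= 0), logical(1))
  if (any(bad)) {
    stop("non-monotonic onsets within trial(s): ",
         paste(names(bad)[bad], collapse = ", "))
  }
  if (!is.null(patternLengths)) {
    L <- patternLengths[as.character(events$block)]
    expBo <- events$seq_position == 1L | events$seq_position == L
    if (!all((events$position_class == "Bo") == expBo)) {
      stop("position_class inconsistent with seq_position boundaries")
    }
  }
  invisible(events)
}

.trialKey <- function(events) {
  interaction(events$subject, events$block, events$trial, drop = TRUE, sep = "/")
}
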
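#' Analysis settings for the end-to-end pipeline
#'
#' All stage parameters in one validated list.  Defaults are the paradigm's
#' analysis constants: 5000 rearrangements for behavioral permutation tests,
#' 1000 iterations for cluster tests, FDR level q = 0.05, family-wise
#' cluster alpha 0.025 per tail, analysis window 0.15-0.37 s tiled by four
#' 55-ms source segments, 5-keystroke error horizon, epochs -1..1 s with
#' the -200..-100 ms baseline, and a 1-100 Hz band-pass.
#'
#' @param nRearrangements rearrangements for behavioral/source permutation
#'   tests.
#' @param clusterIterations iterations for cluster permutation tests.
#' @param q FDR level for multiple-comparison control.
#' @param fweAlpha per-tail family-wise alpha for cluster significance.
#' @param analysisWindow sensor/source analysis window (s, half-open).
#' @param sanityWindow peri-keystroke negative-control window (s).
#' @param segments source segment windows (see \code{\link{segmentWindows}}).
#' @param horizon error-rate window in keystrokes.
#' @param epochWindow epoch extent (s).
#' @param baselineWindow baseline window (s).
#' @param band band-pass edges in Hz; NULL skips filtering.
#' @param combineScheme planar combination scheme ("norm" or "rms").
#' @param nPairs planar-pair positions of the generated sensor layout.
#' @param nGrid,nRegions toy source grid size and region count.
#' @param snr assumed SNR for the default regularization rule.
#' @param seed top-level analysis seed; all stage seeds derive from it.
#' @return list of class \code{runSettings}.
#' @export
runSettings <- function(nRearrangements = 5000, clusterIterations = 1000,
                        q = 0.05, fweAlpha = 0.025,
                        analysisWindow = c(0.15, 0.37),
                        sanityWindow = c(-0.2, 0.15),
                        segments = segmentWindows(),
                        horizon = 5, epochWindow = c(-1, 1),
                        baselineWindow = c(-0.2, -0.1),
                        band = c(1, 100), combineScheme = "norm",
                        nPairs = 16, nGrid = 128, nRegions = 8, snr = 3,
                        seed = 1L) {
  s <- as.list(environment())
  class(s) <- "runSettings"
  s
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes simulate -> behavior -> factorial/pairwise statistics -> ERF
#' (filter, matched-control selection, epoching, baseline, averaging,
#' planar combination) -> cluster statistics -> minimum-norm source
#' contrasts -> region report, and returns a structured report.  All
#' randomness flows from the configuration and settings seeds, so two runs
#' with identical inputs produce identical reports (and identical files
#' when \code{outDir} is given).
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param settings a \code{\link{runSettings}}.
#' @param outDir optional output directory; when given, the event table,
#'   condition summaries, test summaries, cluster tables, the p-threshold
#'   table and region reports are written there as CSV/JSON.
#' @param stages character subset of
#'   \code{c("behavior", "erf", "cluster", "source")}; earlier stages
#'   required by a requested stage are run automatically.
#' @param verbose print progress messages.
#' @return a list report; see Details in the package vignette.
#' @export
runAll <- function(config = simulationConfig(),
                   settings = runSettings(),
                   outDir = NULL,
                   stages = c("behavior", "erf", "cluster", "source"),
                   verbose = interactive()) {
  stopifnot(inherits(config, "SimulationConfig"),
            inherits(settings, "runSettings"))
  stages <- match.arg(stages, several.ok = TRUE)
  say <- function(...) if (verbose) message(...)
  report <- list(provenance = list(
    package = "afmeg",
    version = as.character(utils::packageVersion("afmeg")),
    configSeed = config$seed, analysisSeed = settings$seed))

  say("simulate: generating keystroke performance")
  events <- generatePerformance(config)
  report$events <- list(nKeystrokes = nrow(events),
                        nAf = sum(events$feedback == "AF"),
                        nErrors = sum(events$is_error))

  if ("behavior" %in% stages) {
    say("behavior: condition summaries and factorial tests")
    report$behavior <- .behaviorStage(events, config, settings)
  }

  needErf <- any(c("erf", "cluster", "source") %in% stages)
  if (needErf) {
    say("erf: recordings, matched controls, epoching, averaging")
    erfs <- .erfStage(events, config, settings, say)
    report$erf <- list(trialCounts = erfs$trialCounts,
                       times = erfs$times)
    report$sensorFactorial <- .sensorFactorial(erfs$combined, erfs$times,
                                               settings)
  }

  if ("cluster" %in% stages) {
    say("cluster: spatio-temporal cluster permutation tests")
    report$cluster <- .clusterStage(erfs, settings)
  }

  if ("source" %in% stages) {
    say("source: minimum-norm contrasts and region report")
    report$source <- .sourceStage(erfs, config, settings)
  }

  if (!is.null(outDir)) .writeReport(report, events, outDir)
  report
}

.pairNames <- list(
  "AF-Bo_vs_NF-Bo" = c("AF-Bo", "NF-Bo"),
  "AF-In_vs_NF-In" = c("AF-In", "NF-In"),
  "NF-Bo_vs_NF-In" = c("NF-Bo", "NF-In"),
  "AF-Bo_vs_AF-In" = c("AF-Bo", "AF-In")
)

.behaviorStage <- function(events, config, settings) {
  cs <- conditionSummary(events, horizon = settings$horizon)
  out <- list(conditions = cs$conditions, trials = cs$trials)
  er <- computeErrorRate(events, horizon = settings$horizon)
  di <- computePostFeedbackChange(events)
  metrics <- list(errorRate = conditionCells(er, "rate"),
                  dIOI = conditionCells(di, "mean_dioi"))
  out$factorial <- list()
  out$pairwise <- list()
  off <- 0L
  for (nm in names(metrics)) {
    cells <- metrics[[nm]]
    keep <- stats::complete.cases(cells)
    out$factorial[[nm]] <- factorialPermutationTest(
      cells[keep, , drop = FALSE],
      nRearrangements = settings$nRearrangements,
      seed = .childSeed(settings$seed, 10L + off))
    pw <- list()
    for (pn in names(.pairNames)) {
      cc <- .pairNames[[pn]]
      pw[[pn]] <- pairedPermutationTest(
        cells[keep, cc[1]], cells[keep, cc[2]],
        nRearrangements = settings$nRearrangements,
        seed = .childSeed(settings$seed, 20L + off))
    }
    out$pairwise[[nm]] <- pw
    off <- off + 1L
  }
  lc <- learningCurves(events, afFreeTrials = config$afFreeTrials)
  out$learning <- list(
    cvFirstVsLast = pairedPermutationTest(
      lc$cvPairs$last, lc$cvPairs$first,
      nRearrangements = settings$nRearrangements,
      seed = .childSeed(settings$seed, 30L)),
    halfTempo = if (!anyNA(lc$halfPairs$secondHalf)) {
      pairedPermutationTest(
        lc$halfPairs$firstHalf, lc$halfPairs$secondHalf,
        nRearrangements = settings$nRearrangements,
        seed = .childSeed(settings$seed, 31L))
    },
    pairs = lc)
  out
}

.erfStage <- function(events, config, settings, say = message) {
  layout <- generateSensorLayout(settings$nPairs)
  subjects <- sort(unique(events$subject))
  combined <- NULL; raw <- NULL
  noiseCovs <- vector("list", length(subjects))
  counts <- matrix(0L, length(subjects), 4,
                   dimnames = list(subjects, .CONDITIONS))
  times <- NULL
  for (si in seq_along(subjects)) {
    s <- subjects[si]
    rec <- generateRecordings(events, layout, config, subjects = s)[[1]]
    noiseCovs[[si]] <- estimateNoiseCovariance(rec)
    if (!is.null(settings$band)) {
      rec <- bandpassFilter(rec, settings$band[1], settings$band[2])
    }
    mc <- selectMatchedControls(triggers(rec))
    sel <- sort(unlist(c(mc$af, mc$nf), use.names = FALSE))
    ep <- epochRecording(rec, latencyCorrection = config$midiTriggerDelay,
                         window = settings$epochWindow, select = sel)
    ep <- baselineCorrect(ep, settings$baselineWindow)
    avg <- conditionAverage(ep)
    if (is.null(times)) {
      times <- attr(avg, "times")
      nPos <- nrow(sensorPositions(layout))
      nCh <- 2L * nPos
      combined <- lapply(.CONDITIONS, function(x)
        array(0, c(length(subjects), nPos, length(times))))
      names(combined) <- .CONDITIONS
      raw <- lapply(.CONDITIONS, function(x)
        array(0, c(length(subjects), nCh, length(times))))
      names(raw) <- .CONDITIONS
    }
    for (cc in names(avg)) {
      raw[[cc]][si, , ] <- avg[[cc]]
      combined[[cc]][si, , ] <- combinePlanar(avg[[cc]], layout,
                                              scheme = settings$combineScheme)
      counts[si, cc] <- attr(avg, "counts")[cc]
    }
  }
  list(layout = layout, combined = combined, raw = raw, times = times,
       trialCounts = counts, noiseCovs = noiseCovs,
       channels = channelNames(layout))
}

## sensor-space 2x2 factorial at every (position, sample) in the analysis
## window, with two-stage FDR across points per effect
.sensorFactorial <- function(combined, times, settings) {
  widx <- .windowIndex(times, settings$analysisWindow)
  n <- dim(combined[[1]])[1]
  cellMats <- lapply(.CONDITIONS, function(cc)
    matrix(combined[[cc]][, , widx, drop = FALSE], nrow = n))
  names(cellMats) <- .CONDITIONS
  contr <- list(
    feedback = (cellMats[["NF-Bo"]] + cellMats[["NF-In"]] -
                  cellMats[["AF-Bo"]] - cellMats[["AF-In"]]) / 2,
    position = (cellMats[["NF-Bo"]] - cellMats[["NF-In"]] +
                  cellMats[["AF-Bo"]] - cellMats[["AF-In"]]) / 2,
    interaction = cellMats[["NF-Bo"]] - cellMats[["NF-In"]] -
      cellMats[["AF-Bo"]] + cellMats[["AF-In"]]
  )
  set.seed(.childSeed(settings$seed, 40L))
  out <- lapply(names(contr), function(eff) {
    D <- contr[[eff]]
    obs <- colMeans(D)
    flips <- .flipMatrix(settings$nRearrangements, n)
    null <- abs(flips %*% D) / n
    p <- colMeans(sweep(null, 2, abs(obs) - 1e-12, ">="))
    fdr <- fdrTwoStage(p, q = settings$q)
    list(pThr = fdr$threshold, nSignificant = sum(fdr$rejected))
  })
  names(out) <- names(contr)
  list(pThr = vapply(out, `[[`, numeric(1), "pThr"),
       nSignificant = vapply(out, `[[`, numeric(1), "nSignificant"))
}

.clusterStage <- function(erfs, settings) {
  adj <- adjacency(erfs$layout)
  res <- list(); sanity <- list()
  off <- 0L
  for (pn in names(.pairNames)) {
    cc <- .pairNames[[pn]]
    res[[pn]] <- clusterPermutationTest(
      erfs$combined[[cc[1]]], erfs$combined[[cc[2]]], adj, erfs$times,
      window = settings$analysisWindow,
      nIterations = settings$clusterIterations,
      fweAlpha = settings$fweAlpha,
      seed = .childSeed(settings$seed, 50L + off))
    sanity[[pn]] <- sanityWindowTest(
      erfs$combined[[cc[1]]], erfs$combined[[cc[2]]], adj, erfs$times,
      window = settings$sanityWindow,
      nIterations = settings$clusterIterations,
      fweAlpha = settings$fweAlpha,
      seed = .childSeed(settings$seed, 60L + off))
    off <- off + 1L
  }
  list(main = res, sanity = sanity)
}

.sourceStage <- function(erfs, config, settings) {
  fm <- generateForward(settings$nGrid, erfs$layout,
                        nRegions = settings$nRegions,
                        seed = .childSeed(settings$seed, 70L))
  n <- dim(erfs$raw[[1]])[1]
  ## per-subject inverse with the subject's own noise covariance
  segArrays <- lapply(.CONDITIONS, function(cc)
    array(0, c(n, settings$nGrid, length(settings$segments)),
          dimnames = list(NULL, NULL, names(settings$segments))))
  names(segArrays) <- .CONDITIONS
  for (si in seq_len(n)) {
    inv <- buildInverse(fm, erfs$noiseCovs[[si]], snr = settings$snr)
    for (cc in .CONDITIONS) {
      est <- applyInverse(inv, erfs$raw[[cc]][si, , ], times = erfs$times)
      segArrays[[cc]][si, , ] <- sourceSegmentMeans(est, settings$segments)
    }
  }
  contrasts <- list(); regions <- list()
  off <- 0L
  for (pn in names(.pairNames)) {
    cc <- .pairNames[[pn]]
    sc <- segmentContrastTest(segArrays[[cc[1]]], segArrays[[cc[2]]],
                              segments = settings$segments,
                              nRearrangements = settings$nRearrangements,
                              q = settings$q,
                              seed = .childSeed(settings$seed, 80L + off))
    contrasts[[pn]] <- sc
    regions[[pn]] <- regionReport(sc, fm)
    off <- off + 1L
  }
  pThrTable <- do.call(rbind, lapply(contrasts, `[[`, "pThrTable"))
  list(forward = fm, contrasts = contrasts, regions = regions,
       pThrTable = pThrTable)
}

.writeReport <- function(report, events, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeEventTable(events, file.path(outDir, "events.tsv"))
  if (!is.null(report$behavior)) {
    utils::write.csv(report$behavior$conditions,
                     file.path(outDir, "behavior_conditions.csv"),
                     row.names = FALSE)
    utils::write.csv(report$behavior$trials,
                     file.path(outDir, "behavior_trials.csv"),
                     row.names = FALSE)
    fac <- do.call(rbind, lapply(names(report$behavior$factorial), function(nm) {
      f <- report$behavior$factorial[[nm]]
      data.frame(metric = nm, effect = names(f$p.values),
                 contrast = as.numeric(f$observed),
                 p = as.numeric(f$p.values))
    }))
    utils::write.csv(fac, file.path(outDir, "behavior_factorial.csv"),
                     row.names = FALSE)
    for (nm in names(report$behavior$pairwise)) {
      writePermutationSummary(report$behavior$pairwise[[nm]],
                              file.path(outDir,
                                        paste0("behavior_pairwise_", nm, ".csv")))
    }
  }
  if (!is.null(report$erf)) {
    utils::write.csv(as.data.frame(report$erf$trialCounts),
                     file.path(outDir, "erf_trial_counts.csv"))
  }
  if (!is.null(report$sensorFactorial)) {
    jsonlite::write_json(report$sensorFactorial,
                         file.path(outDir, "sensor_factorial.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  if (!is.null(report$cluster)) {
    for (pn in names(report$cluster$main)) {
      writeClusterReport(report$cluster$main[[pn]],
                         file.path(outDir, paste0("cluster_", pn)))
      writeClusterReport(report$cluster$sanity[[pn]],
                         file.path(outDir, paste0("cluster_sanity_", pn)))
    }
  }
  if (!is.null(report$source)) {
    utils::write.csv(as.data.frame(report$source$pThrTable),
                     file.path(outDir, "source_pthr.csv"))
    for (pn in names(report$source$regions)) {
      utils::write.csv(report$source$regions[[pn]],
                       file.path(outDir, paste0("regions_", pn, ".csv")),
                       row.names = FALSE)
    }
  }
  invisible(outDir)
}
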
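## Plain-text serialization.  Arrays and tables go to CSV/TSV with
## full-precision numerics, metadata to JSON, configurations to YAML, so
## every artifact is diffable and round-trips exactly.

.fmtNum <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) df[[nm]] <- sprintf("%.17g", df[[nm]])
  }
  df
}

#' Write / read a keystroke event table
#'
#' Tab-separated with header; numeric columns at full (17 significant
#' digits) precision so a write-read round trip is exact.
#'
#' @param events keystroke event table.
#' @param path file path (.tsv).
#' @return \code{readEventTable} returns the validated table.
#' @export
writeEventTable <- function(events, path) {
  validateEventTable(events)
  utils::write.table(.fmtNum(events), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeEventTable
#' @export
readEventTable <- function(path) {
  ev <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if ("is_error" %in% names(ev)) ev$is_error <- as.logical(ev$is_error)
  if ("gt_error_injected" %in% names(ev)) {
    ev$gt_error_injected <- as.logical(ev$gt_error_injected)
  }
  validateEventTable(ev)
  ev
}

#' Write / read a simulation configuration (YAML)
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param path file path (.yaml).
#' @export
writeSimulationConfig <- function(config, path) {
  stopifnot(inherits(config, "SimulationConfig"))
  x <- unclass(config)
  x$slowingEffect <- as.list(x$slowingEffect)
  x$errorBoost <- as.list(x$errorBoost)
  x$erfEffects <- lapply(x$erfEffects, unclass)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname writeSimulationConfig
#' @export
readSimulationConfig <- function(path) {
  x <- yaml::read_yaml(path)
  need <- c("nSubjects", "sequencePatterns", "trialsPerBlock")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("config file is missing field(s): ", paste(miss, collapse = ", "))
  }
  x$slowingEffect <- unlist(x$slowingEffect)
  x$errorBoost <- unlist(x$errorBoost)
  x$erfEffects <- lapply(x$erfEffects, function(e) do.call(erfEffect, e))
  do.call(simulationConfig, x)
}

#' Write / read a sensor layout bundle
#'
#' Directory with \code{positions.csv}, \code{pairs.csv},
#' \code{adjacency.csv}, \code{groups.json} and \code{meta.json}.
#'
#' @param layout a \code{\link{SensorLayout-class}}.
#' @param dir directory path (created if needed).
#' @export
writeSensorLayout <- function(layout, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pos <- data.frame(position = rownames(sensorPositions(layout)),
                    sensorPositions(layout))
  utils::write.csv(.fmtNum(pos), file.path(dir, "positions.csv"),
                   row.names = FALSE)
  utils::write.csv(pairMap(layout), file.path(dir, "pairs.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(adjacency(layout)),
                   file.path(dir, "adjacency.csv"), row.names = FALSE)
  jsonlite::write_json(sensorGroups(layout), file.path(dir, "groups.json"))
  jsonlite::write_json(list(threshold = layout@threshold),
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname writeSensorLayout
#' @export
readSensorLayout <- function(dir) {
  pos <- utils::read.csv(file.path(dir, "positions.csv"))
  m <- as.matrix(pos[, c("x", "y")])
  rownames(m) <- pos$position
  adj <- as.matrix(utils::read.csv(file.path(dir, "adjacency.csv")))
  if (nrow(adj) == 0) adj <- matrix(integer(), 0, 2)
  colnames(adj) <- c("from", "to")
  groups <- lapply(jsonlite::read_json(file.path(dir, "groups.json")),
                   function(g) as.integer(unlist(g)))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  new("SensorLayout", positions = m,
      pairMap = utils::read.csv(file.path(dir, "pairs.csv"),
                                stringsAsFactors = FALSE),
      adjacency = adj, threshold = as.numeric(meta$threshold),
      groups = groups)
}

#' Write / read an epoch set bundle
#'
#' Directory with \code{data.csv} (one row per trial x channel),
#' \code{covariates.csv} and \code{meta.json} (times, sampling rate,
#' condition labels, subject, combined flag).
#'
#' @param epochs an \code{\link{EpochSet-class}}.
#' @param dir directory path.
#' @export
writeEpochSet <- function(epochs, dir) {
  stopifnot(is(epochs, "EpochSet"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(epochs@data)
  flat <- matrix(aperm(epochs@data, c(2, 1, 3)), d[1] * d[2], d[3])
  df <- data.frame(trial = rep(seq_len(d[1]), each = d[2]),
                   channel = rep(dimnames(epochs@data)[[2]], d[1]),
                   flat, check.names = FALSE)
  names(df)[-(1:2)] <- paste0("s", seq_len(d[3]))
  utils::write.csv(.fmtNum(df), file.path(dir, "data.csv"), row.names = FALSE)
  utils::write.csv(.fmtNum(epochs@covariates),
                   file.path(dir, "covariates.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(times = epochs@times, sfreq = epochs@sfreq,
         conditions = as.character(epochs@conditions),
         conditionLevels = levels(epochs@conditions),
         subject = epochs@subject, combined = epochs@combined),
    file.path(dir, "meta.json"), digits = NA, auto_unbox = TRUE,
    null = "null")
  invisible(dir)
}

#' @rdname writeEpochSet
#' @export
readEpochSet <- function(dir) {
  df <- utils::read.csv(file.path(dir, "data.csv"), check.names = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  trials <- sort(unique(df$trial))
  chans <- unique(df$channel)
  nT <- sum(grepl("^s[0-9]+$", names(df)))
  arr <- array(0, c(length(trials), length(chans), nT),
               dimnames = list(NULL, chans, NULL))
  mat <- as.matrix(df[, paste0("s", seq_len(nT))])
  for (i in seq_len(nrow(df))) {
    arr[match(df$trial[i], trials), match(df$channel[i], chans), ] <- mat[i, ]
  }
  cova <- utils::read.csv(file.path(dir, "covariates.csv"))
  if (!nrow(cova)) cova <- data.frame(row.names = seq_along(trials))
  new("EpochSet", data = arr, times = as.numeric(meta$times),
      sfreq = as.numeric(meta$sfreq),
      conditions = factor(meta$conditions, levels = meta$conditionLevels),
      covariates = cova,
      subject = if (is.null(meta$subject)) NULL else as.character(meta$subject),
      combined = isTRUE(meta$combined))
}

#' Write / read a forward-model bundle
#'
#' Directory with \code{leadfield.csv} (channels x grid, channel names in
#' the first column), \code{grid.csv} (coordinates + region label) and
#' \code{adjacency.csv}.
#'
#' @param fm a \code{\link{ForwardModel-class}}.
#' @param dir directory path.
#' @export
writeForwardModel <- function(fm, dir) {
  stopifnot(is(fm, "ForwardModel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  L <- leadfield(fm)
  df <- data.frame(channel = rownames(L), L, check.names = FALSE)
  names(df)[-1] <- paste0("g", seq_len(ncol(L)))
  utils::write.csv(.fmtNum(df), file.path(dir, "leadfield.csv"),
                   row.names = FALSE)
  grid <- data.frame(gridCoords(fm), region = as.character(regionLabels(fm)))
  utils::write.csv(.fmtNum(grid), file.path(dir, "grid.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(adjacency(fm)),
                   file.path(dir, "adjacency.csv"), row.names = FALSE)
  jsonlite::write_json(list(regionLevels = levels(regionLabels(fm))),
                       file.path(dir, "meta.json"))
  invisible(dir)
}

#' @rdname writeForwardModel
#' @export
readForwardModel <- function(dir) {
  df <- utils::read.csv(file.path(dir, "leadfield.csv"), check.names = FALSE)
  L <- as.matrix(df[, -1])
  rownames(L) <- df$channel
  colnames(L) <- NULL
  grid <- utils::read.csv(file.path(dir, "grid.csv"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  adj <- as.matrix(utils::read.csv(file.path(dir, "adjacency.csv")))
  if (nrow(adj) == 0) adj <- matrix(integer(), 0, 2)
  colnames(adj) <- c("from", "to")
  new("ForwardModel", leadfield = L,
      gridCoords = as.matrix(grid[, c("x", "y", "z")]),
      regionLabels = factor(grid$region, levels = unlist(meta$regionLevels)),
      gridAdjacency = adj)
}

#' Export a cluster test result
#'
#' CSV cluster table plus a JSON file with full membership and parameters.
#'
#' @param ct a \code{clusterTest}.
#' @param prefix path prefix; writes \code{<prefix>.csv} and
#'   \code{<prefix>.json}.
#' @export
writeClusterReport <- function(ct, prefix) {
  stopifnot(inherits(ct, "clusterTest"))
  utils::write.csv(ct$clusters, paste0(prefix, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(clusters = ct$clusters,
         members = lapply(ct$members, function(m) as.data.frame(m)),
         params = ct$params[c("window", "nIterations", "fweAlpha",
                              "tThreshold", "n")]),
    paste0(prefix, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(prefix)
}

#' Export a permutation-test summary row
#' @param tests named list of \code{permTest} objects.
#' @param path CSV path.
#' @export
writePermutationSummary <- function(tests, path) {
  df <- do.call(rbind, lapply(names(tests), function(nm) {
    t <- tests[[nm]]
    data.frame(comparison = nm, statistic = t$statistic, p = t$p.value,
               ps_dep = t$psDep, n = t$n,
               n_rearrangements = t$nRearrangements)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
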
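## Independent brute-force oracles used to cross-check the package's
## statistics.  These deliberately use naive nested loops / enumeration and
## share no code with the implementation.

## window-scan oracle for the 5-keystroke error-rate statistic
oracleErrorRate <- function(events, horizon = 5) {
  rows <- list()
  for (s in unique(events$subject)) {
    for (fb in c("NF", "AF")) for (cl in c("Bo", "In")) {
      nEv <- 0L; nInd <- 0L
      sub <- events[events$subject == s, , drop = FALSE]
      for (b in unique(sub$block)) for (tr in unique(sub$trial[sub$block == b])) {
        t <- sub[sub$block == b & sub$trial == tr, , drop = FALSE]
        t <- t[order(t$keystroke), , drop = FALSE]
        for (i in seq_len(nrow(t))) {
          if (t$feedback[i] != fb || t$position_class[i] != cl) next
          win <- seq(i + 1, min(i + horizon, nrow(t)))
          if (i + 1 > nrow(t)) win <- integer()
          if (any(t$feedback[win] == "AF")) next   # excluded
          nEv <- nEv + 1L
          if (any(t$is_error[win])) nInd <- nInd + 1L
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, feedback = fb, position_class = cl,
        n_events = nEv, n_induced = nInd,
        rate = if (nEv > 0) nInd / nEv else NA_real_)
    }
  }
  do.call(rbind, rows)
}

## brute-force post-feedback delta-IOI oracle
oracleDeltaIOI <- function(events) {
  vals <- list()
  for (s in unique(events$subject)) {
    sub <- events[events$subject == s, , drop = FALSE]
    for (b in unique(sub$block)) for (tr in unique(sub$trial[sub$block == b])) {
      t <- sub[sub$block == b & sub$trial == tr, , drop = FALSE]
      t <- t[order(t$keystroke), , drop = FALSE]
      on <- t$onset_ms
      ioi <- c(NA, diff(on))
      lastAf <- -Inf
      for (i in seq_len(nrow(t))) {
        if (t$feedback[i] == "AF") lastAf <- i
        skip <- t$feedback[i] == "NF" && (i - lastAf) %in% c(1, 2)
        if (i >= 2 && i + 1 <= nrow(t) && !skip) {
          vals[[length(vals) + 1L]] <- data.frame(
            subject = s, feedback = t$feedback[i],
            position_class = t$position_class[i],
            d = ioi[i + 1] - ioi[i])
        }
      }
    }
  }
  v <- do.call(rbind, vals)
  aggregate(list(mean_dioi = v$d),
            by = list(subject = v$subject, feedback = v$feedback,
                      position_class = v$position_class), FUN = mean)
}

## two-pass cvIOI oracle for one trial's onset vector
oracleCvIOI <- function(onsets) {
  ioi <- onsets[-1] - onsets[-length(onsets)]
  m <- sum(ioi) / length(ioi)
  s <- sqrt(sum((ioi - m)^2) / (length(ioi) - 1))
  s / m
}

## exhaustive sign-flip p-value for paired data (two-sided, >= convention)
oracleExhaustiveP <- function(d) {
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  stats <- abs(signs %*% d) / n
  mean(stats >= abs(mean(d)) - 1e-12)
}

## hand-stepped two-stage adaptive linear step-up oracle
oracleTwoStageFdr <- function(p, q = 0.05) {
  m <- length(p)
  bh <- function(p, a) {
    o <- order(p); k <- 0
    for (i in seq_len(m)) if (p[o][i] <= a * i / m) k <- i
    if (k == 0) rep(FALSE, m) else p <= p[o][k]
  }
  q1 <- q / (1 + q)
  r1 <- sum(bh(p, q1))
  if (r1 == 0) return(list(threshold = 0, rejected = rep(FALSE, m)))
  if (r1 == m) return(list(threshold = max(p), rejected = rep(TRUE, m)))
  rej <- bh(p, q1 * m / (m - r1))
  list(threshold = if (any(rej)) max(p[rej]) else 0, rejected = rej)
}

## connected components of a suprathreshold mask via igraph (flood fill)
oracleClusters <- function(tmap, adjacency, threshold) {
  S <- nrow(tmap); T <- ncol(tmap)
  out <- list()
  for (sgn in c(1, -1)) {
    mask <- if (sgn > 0) tmap > threshold else tmap < -threshold
    idx <- which(mask)
    if (!length(idx)) next
    g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
    lin2node <- integer(S * T); lin2node[idx] <- seq_along(idx)
    edges <- integer()
    for (a in idx) {
      s <- ((a - 1) %% S) + 1; t <- ((a - 1) %/% S) + 1
      ## temporal neighbour
      if (t < T) {
        b <- a + S
        if (b %in% idx) edges <- c(edges, lin2node[a], lin2node[b])
      }
      ## spatial neighbours
      if (nrow(adjacency)) for (k in seq_len(nrow(adjacency))) {
        nb <- NA
        if (adjacency[k, 1] == s) nb <- adjacency[k, 2]
        if (adjacency[k, 2] == s) nb <- adjacency[k, 1]
        if (!is.na(nb)) {
          b <- nb + (t - 1) * S
          if (b %in% idx) edges <- c(edges, lin2node[a], lin2node[b])
        }
      }
    }
    if (length(edges)) g <- igraph::add_edges(g, edges)
    comp <- igraph::components(g)$membership
    for (cid in unique(comp)) {
      mem <- sort(idx[comp == cid])
      out[[length(out) + 1L]] <- list(members = mem, mass = sum(tmap[mem]),
                                      sign = sgn)
    }
  }
  out
}

## canonical form for cluster comparison: sorted linear member indices
clusterKey <- function(cl, S) {
  mem <- sort(cl$members[, "sensor"] + (cl$members[, "time"] - 1L) * S)
  paste(mem, collapse = ",")
}

## small random event table with known structure (for oracle comparisons)
randomEventTable <- function(nTrials = 3, nKey = 25, pErr = 0.15, pAf = 0.12,
                             nSubj = 2) {
  rows <- list()
  for (s in seq_len(nSubj)) for (tr in seq_len(nTrials)) {
    onset <- cumsum(c(0, runif(nKey - 1, 200, 400)))
    pos <- rep_len(1:4, nKey)
    rows[[length(rows) + 1L]] <- data.frame(
      subject = s, block = 1L, trial = tr, keystroke = seq_len(nKey),
      onset_ms = onset, pitch_played = 60L + pos, pitch_heard = 60L + pos,
      velocity = rnorm(nKey, 64, 8), seq_position = pos,
      position_class = ifelse(pos %in% c(1, 4), "Bo", "In"),
      feedback = ifelse(runif(nKey) < pAf, "AF", "NF"),
      is_error = runif(nKey) < pErr, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

## tiny simulation config for fast tests
tinyConfig <- function(...) {
  args <- list(...)
  defaults <- list(nSubjects = 2,
                   sequencePatterns = defaultSequencePatterns()[1:2],
                   trialsPerBlock = 4, trialDuration = 8,
                   afFreeTrials = c(1), seed = 42)
  do.call(simulationConfig, utils::modifyList(defaults, args))
}
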
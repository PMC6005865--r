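#' Pointwise dependent-samples t-map
#'
#' Paired t statistic at every (sensor position, time sample):
#' t = mean(d) / (sd(d)/sqrt(n)) with d the per-subject condition
#' difference A - B.  Points with zero variance get +/-Inf (handled by the
#' cluster-forming threshold) or 0 when the mean difference is also zero.
#'
#' @param a,b numeric arrays, subjects x positions x time (same dims).
#' @return numeric matrix positions x time of t-values.
#' @export
pointwiseDependentT <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("a and b must have identical dimensions")
  n <- dim(a)[1]
  if (n < 2) stop("need at least 2 subjects")
  d <- a - b
  dm <- matrix(d, nrow = n)
  m <- colMeans(dm)
  ss <- colSums(dm^2)
  v <- pmax(ss - n * m^2, 0) / (n - 1)
  ## constant differences (relative variance at rounding level) count as
  ## zero-variance points
  v[v < ss * 1e-14] <- 0
  tval <- ifelse(v > 0, m / sqrt(v / n),
                 ifelse(m == 0, 0, sign(m) * Inf))
  matrix(tval, dim(a)[2], dim(a)[3])
}

#' Find spatio-temporal clusters in a t-map
#'
#' Groups suprathreshold points (t > threshold and t < -threshold handled
#' separately) into connected components of the sensor-adjacency x
#' consecutive-time-sample graph: two points are neighbours when they share
#' the time sample and their sensors are spatially adjacent, or share the
#' sensor and sit at consecutive samples.  Cluster mass is the sum of
#' member t-values (signed).
#'
#' @param tmap positions x time t-value matrix.
#' @param adjacency two-column matrix of spatially adjacent position pairs.
#' @param threshold positive cluster-forming threshold.
#' @return list of clusters, each with \code{members} (two-column matrix:
#'   sensor, time), \code{mass} and \code{sign} (+1/-1); ordered by
#'   decreasing |mass|.  Empty list when nothing is suprathreshold.
#' @export
findClusters <- function(tmap, adjacency, threshold) {
  .assertScalar(threshold, "threshold", lower = .Machine$double.eps)
  pos <- .maskClusters(tmap > threshold, adjacency, tmap, +1)
  neg <- .maskClusters(tmap < -threshold, adjacency, tmap, -1)
  out <- c(pos, neg)
  if (length(out) > 1) {
    out <- out[order(vapply(out, function(cl) -abs(cl$mass), numeric(1)))]
  }
  out
}

## connected components over a logical mask (positions x time)
.maskClusters <- function(mask, adjacency, tmap, sgn) {
  idx <- which(mask)
  if (!length(idx)) return(list())
  S <- nrow(mask); T <- ncol(mask)
  comp <- .linearComponents(mask, adjacency, S, T)
  unname(lapply(split(idx, comp[idx]), function(mem) {
    list(members = cbind(sensor = ((mem - 1L) %% S) + 1L,
                         time = ((mem - 1L) %/% S) + 1L),
         mass = sum(tmap[mem]), sign = sgn)
  }))
}

## union-find over the linear indices of the masked points
.linearComponents <- function(mask, adjacency, S, T) {
  idx <- which(mask)
  id <- integer(S * T)
  id[idx] <- seq_along(idx)
  parent <- seq_along(idx)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <<- ri
  }
  ## temporal edges: same sensor, consecutive samples
  if (T > 1) {
    e <- which(mask[, -T, drop = FALSE] & mask[, -1, drop = FALSE])
    for (lin in e) unite(id[lin], id[lin + S])
  }
  ## spatial edges: adjacent sensors, same sample
  if (nrow(adjacency)) {
    for (k in seq_len(nrow(adjacency))) {
      a <- adjacency[k, 1]; b <- adjacency[k, 2]
      cols <- which(mask[a, ] & mask[b, ])
      for (cc in cols) unite(id[a + (cc - 1L) * S], id[b + (cc - 1L) * S])
    }
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  comp <- integer(S * T)
  comp[idx] <- roots
  comp
}

## max positive cluster mass and min (most negative) cluster mass in a t-map
.maxClusterMass <- function(tmap, adjacency, threshold) {
  cl <- findClusters(tmap, adjacency, threshold)
  masses <- vapply(cl, `[[`, numeric(1), "mass")
  c(pos = if (any(masses > 0)) max(masses) else 0,
    neg = if (any(masses < 0)) min(masses) else 0)
}

#' Spatio-temporal cluster-based permutation test
#'
#' Tests a paired condition contrast on combined-planar ERFs over a time
#' window (default 0.15-0.37 s post-keystroke) with the max-cluster-mass
#' permutation procedure: suprathreshold clusters of the observed paired
#' t-map are evaluated against the Monte-Carlo distribution of the maximum
#' cluster mass under per-subject random condition swaps (sign flips of the
#' subject difference maps), separately per sign with a family-wise error
#' criterion of \code{fweAlpha} per tail (0.025 each for a two-sided test).
#'
#' @param a,b subjects x positions x time arrays of per-subject
#'   condition-average ERFs (same subject order).
#' @param adjacency spatial adjacency (two-column matrix of position pairs),
#'   e.g. \code{adjacency(layout)}.
#' @param times time axis in seconds for the third dimension.
#' @param window analysis window in seconds, half-open.
#' @param nIterations Monte-Carlo iterations for the null distribution.
#' @param fweAlpha per-tail family-wise alpha for flagging significance.
#' @param clusterAlpha per-point alpha defining the cluster-forming
#'   threshold (two-tailed paired-t critical value, df = n - 1).
#' @param tThreshold directly sets the cluster-forming threshold
#'   (overrides \code{clusterAlpha}).
#' @param seed integer seed.
#' @return object of class \code{clusterTest}: \code{clusters} (data.frame:
#'   id, sign, mass, p, n_points, t_from, t_to), \code{members} (list of
#'   member matrices with window-relative and absolute time indices),
#'   \code{nullPos}, \code{nullNeg}, and the parameters.
#' @export
clusterPermutationTest <- function(a, b, adjacency, times,
                                   window = c(0.15, 0.37),
                                   nIterations = 1000, fweAlpha = 0.025,
                                   clusterAlpha = 0.05, tThreshold = NULL,
                                   seed = NULL) {
  if (!identical(dim(a), dim(b))) stop("a and b must have identical dimensions")
  if (dim(a)[3] != length(times)) stop("times must match the third dimension")
  widx <- .windowIndex(times, window)
  if (!length(widx)) stop("analysis window outside the epoch timebase")
  n <- dim(a)[1]
  if (n < 2) stop("need at least 2 subjects")
  if (is.null(tThreshold)) tThreshold <- qt(1 - clusterAlpha / 2, df = n - 1)

  aw <- a[, , widx, drop = FALSE]
  bw <- b[, , widx, drop = FALSE]
  S <- dim(aw)[2]; Tw <- dim(aw)[3]
  D <- matrix(aw - bw, nrow = n)        # n x (S*Tw), column-major (sensor fastest)
  ss <- colSums(D^2)

  tFromFlips <- function(f) {
    m <- as.numeric(f %*% D) / n
    v <- pmax(ss - n * m^2, 0) / (n - 1)
    v[v < ss * 1e-14] <- 0
    tv <- ifelse(v > 0, m / sqrt(v / n), ifelse(m == 0, 0, sign(m) * Inf))
    matrix(tv, S, Tw)
  }

  tObs <- tFromFlips(matrix(1, 1, n))
  obsClusters <- findClusters(tObs, adjacency, tThreshold)

  .setSeed(seed)
  nullPos <- numeric(nIterations)
  nullNeg <- numeric(nIterations)
  for (i in seq_len(nIterations)) {
    f <- matrix(sample(c(-1, 1), n, replace = TRUE), 1, n)
    mm <- .maxClusterMass(tFromFlips(f), adjacency, tThreshold)
    nullPos[i] <- mm["pos"]
    nullNeg[i] <- mm["neg"]
  }

  rows <- lapply(seq_along(obsClusters), function(i) {
    cl <- obsClusters[[i]]
    p <- if (cl$sign > 0) mean(nullPos >= cl$mass) else mean(nullNeg <= cl$mass)
    data.frame(id = i, sign = cl$sign, mass = cl$mass, p = p,
               n_points = nrow(cl$members),
               t_from = times[widx[min(cl$members[, "time"])]],
               t_to = times[widx[max(cl$members[, "time"])]],
               significant = p < fweAlpha)
  })
  members <- lapply(obsClusters, function(cl) {
    cbind(cl$members, time_abs = widx[cl$members[, "time"]])
  })
  structure(list(
    clusters = if (length(rows)) do.call(rbind, rows) else
      data.frame(id = integer(), sign = numeric(), mass = numeric(),
                 p = numeric(), n_points = integer(), t_from = numeric(),
                 t_to = numeric(), significant = logical()),
    members = members, tObs = tObs, windowIndex = widx,
    nullPos = nullPos, nullNeg = nullNeg,
    params = list(window = window, nIterations = nIterations,
                  fweAlpha = fweAlpha, tThreshold = tThreshold,
                  n = n, seed = seed)
  ), class = "clusterTest")
}

#' @export
print.clusterTest <- function(x, ...) {
  cat("Spatio-temporal cluster permutation test\n")
  p <- x$params
  cat(sprintf("  window [%.3f, %.3f) s, |t| > %.3f, %d iterations, alpha = %.3f per tail\n",
              p$window[1], p$window[2], p$tThreshold, p$nIterations, p$fweAlpha))
  if (!nrow(x$clusters)) {
    cat("  no suprathreshold clusters\n")
  } else {
    print(x$clusters, row.names = FALSE)
  }
  invisible(x)
}

#' Peri-keystroke sanity-window cluster test
#'
#' Runs the identical cluster permutation machinery on the peri-keystroke
#' interval (default -0.2 to 0.15 s).  Used as a negative control: effects
#' of interest live after 0.15 s, so this window should come back clean.
#'
#' @inheritParams clusterPermutationTest
#' @return a \code{clusterTest} object.
#' @export
sanityWindowTest <- function(a, b, adjacency, times,
                             window = c(-0.2, 0.15), ...) {
  clusterPermutationTest(a, b, adjacency, times, window = window, ...)
}
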
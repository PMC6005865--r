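#' Estimate the sensor noise covariance
#'
#' Sample covariance of no-performance baseline data (the silent pre-trial
#' intervals), with diagonal loading
#' \code{epsilon * trace(C) / nSensors} added for positive definiteness.
#'
#' @param x channels x samples matrix, a list of such segments (columns are
#'   concatenated), or a \code{\link{ContinuousRecording-class}} (its
#'   pre-trial baseline intervals are used).
#' @param epsilon diagonal-loading factor.
#' @return symmetric positive-definite covariance matrix with attribute
#'   \code{epsilon}; warns when fewer than nSensors + 1 samples are
#'   available.
#' @export
estimateNoiseCovariance <- function(x, epsilon = 1e-3) {
  if (is(x, "ContinuousRecording")) {
    x <- .baselineSegments(x)
  }
  if (is.list(x)) x <- do.call(cbind, x)
  if (!is.matrix(x) || ncol(x) == 0) stop("empty baseline data")
  nCh <- nrow(x)
  if (ncol(x) < nCh + 1) {
    warning("fewer baseline samples than sensors + 1; covariance estimate ",
            "relies heavily on the diagonal loading")
  }
  xc <- x - rowMeans(x)
  C <- tcrossprod(xc) / max(1, ncol(x) - 1)
  C <- (C + t(C)) / 2
  C <- C + diag(epsilon * sum(diag(C)) / nCh, nCh)
  dimnames(C) <- list(rownames(x), rownames(x))
  attr(C, "epsilon") <- epsilon
  C
}

.baselineSegments <- function(recording) {
  dat <- recordingData(recording)
  sfreq <- samplingRate(recording)
  iv <- baselineIntervals(recording)
  segs <- lapply(seq_len(nrow(iv)), function(i) {
    s <- max(1L, floor(iv[i, 1] / 1000 * sfreq) + 1L)
    e <- min(ncol(dat), floor(iv[i, 2] / 1000 * sfreq))
    if (e <= s) return(NULL)
    dat[, s:e, drop = FALSE]
  })
  do.call(cbind, segs[!vapply(segs, is.null, logical(1))])
}

#' Default regularization parameter
#'
#' The signal-to-noise based rule for the Tikhonov parameter of the L2
#' minimum-norm inverse: \code{lambda^2 = trace(L L') / (trace(C) * snr^2)},
#' which reduces to the familiar \code{trace(L L')/(nSensors * snr^2)} for a
#' whitened (identity) noise covariance.
#'
#' @param L leadfield matrix (sensors x grid).
#' @param C noise covariance.
#' @param snr assumed amplitude signal-to-noise ratio.
#' @return the scalar lambda.
#' @export
lambdaDefault <- function(L, C, snr = 3) {
  sqrt(sum(L^2) / (sum(diag(C)) * snr^2))
}

#' Build the L2 minimum-norm inverse operator
#'
#' With identity source covariance the minimum-norm inverse is
#' \code{M = L' (L L' + lambda^2 C)^{-1}}.  At \code{lambda = 0} with a
#' rank-deficient \code{L L'} the Moore-Penrose pseudoinverse is used
#' instead (logged via a message), which yields the classical minimum-norm
#' solution on the row space of \code{L}.
#'
#' @param x a \code{\link{ForwardModel-class}} or a leadfield matrix.
#' @param noiseCov sensor noise covariance (identity if NULL).
#' @param lambda regularization scalar >= 0; default from
#'   \code{\link{lambdaDefault}} with \code{snr}.
#' @param snr assumed SNR for the default lambda rule.
#' @param depthWeight if TRUE, uses a diagonal source covariance
#'   proportional to the inverse squared column norms of the leadfield
#'   (classical depth weighting) instead of the identity.
#' @return an \code{\link{InverseOperator-class}}.
#' @examples
#' lay <- generateSensorLayout(9)
#' fm <- generateForward(50, lay, seed = 2)
#' inv <- buildInverse(fm, lambda = 0.1)
#' inv
#' @export
buildInverse <- function(x, noiseCov = NULL, lambda = NULL, snr = 3,
                         depthWeight = FALSE) {
  L <- if (is(x, "ForwardModel")) leadfield(x) else x
  nCh <- nrow(L)
  if (is.null(noiseCov)) noiseCov <- diag(nCh)
  if (!identical(dim(noiseCov), as.integer(c(nCh, nCh)))) {
    stop("noiseCov dimensions must match the sensor count")
  }
  w <- if (depthWeight) 1 / colSums(L^2) else rep(1, ncol(L))
  if (is.null(lambda)) lambda <- lambdaDefault(L, noiseCov, snr)
  .assertScalar(lambda, "lambda", lower = 0)
  LR <- L * rep(w, each = nCh)           # L %*% diag(w)
  G <- LR %*% t(L) + lambda^2 * noiseCov
  pseudo <- FALSE
  M <- tryCatch({
    if (rcond(G) < 1e-12) stop("ill-conditioned")
    t(LR) %*% solve(G)
  }, error = function(e) {
    message("gram matrix singular at lambda = ", format(lambda),
            "; using pseudoinverse fallback")
    pseudo <<- TRUE
    t(LR) %*% .pinv(G)
  })
  new("InverseOperator", matrix = M, lambda = lambda,
      noiseCov = unclass(noiseCov), pseudoinverse = pseudo)
}

## Moore-Penrose pseudoinverse via SVD
.pinv <- function(A, tol = NULL) {
  s <- svd(A)
  if (is.null(tol)) tol <- max(dim(A)) * .Machine$double.eps * max(s$d)
  keep <- s$d > tol
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Apply an inverse operator to sensor data
#'
#' Linear mapping of sensor fields to distributed source currents,
#' \code{s(t) = M b(t)}.
#'
#' @param op an \code{\link{InverseOperator-class}}.
#' @param b sensor data: channels x time matrix or an
#'   \code{\link{EpochSet-class}} (applied per trial; returns a list of
#'   \code{SourceEstimate}s).
#' @param times time axis for matrix input (optional).
#' @return a \code{\link{SourceEstimate-class}} (or list thereof).
#' @export
applyInverse <- function(op, b, times = NULL) {
  stopifnot(is(op, "InverseOperator"))
  if (is(b, "EpochSet")) {
    return(lapply(seq_len(dim(b)[1]), function(i) {
      new("SourceEstimate", currents = op@matrix %*% b@data[i, , ],
          times = b@times)
    }))
  }
  if (!is.matrix(b)) b <- matrix(b, ncol = 1)
  if (nrow(b) != ncol(op@matrix)) stop("sensor dimension mismatch")
  if (is.null(times)) times <- seq_len(ncol(b))
  new("SourceEstimate", currents = op@matrix %*% b, times = times)
}

#' Segment windows tiling an analysis interval
#'
#' Half-open segments of equal width tiling [start, start + n*width);
#' the default four 55-ms segments tile 0.15-0.37 s exactly.
#'
#' @param start interval start in seconds.
#' @param width segment width in seconds.
#' @param n number of segments.
#' @return list of \code{c(from, to)} windows named S1..Sn.
#' @export
segmentWindows <- function(start = 0.15, width = 0.055, n = 4) {
  out <- lapply(seq_len(n) - 1, function(i) c(start + i * width,
                                              start + (i + 1) * width))
  names(out) <- paste0("S", seq_len(n))
  out
}

#' Segment-mean source currents
#'
#' @param est a \code{\link{SourceEstimate-class}}.
#' @param segments list of half-open windows (see
#'   \code{\link{segmentWindows}}).
#' @return grid x segments matrix of mean currents.
#' @export
sourceSegmentMeans <- function(est, segments = segmentWindows()) {
  stopifnot(is(est, "SourceEstimate"))
  out <- vapply(segments, function(w) {
    idx <- .windowIndex(est@times, w)
    if (!length(idx)) stop("segment [", w[1], ", ", w[2],
                           ") outside the source timebase")
    rowMeans(est@currents[, idx, drop = FALSE])
  }, numeric(nrow(est@currents)))
  colnames(out) <- names(segments)
  out
}

#' Per-segment permutation contrasts on source currents with FDR control
#'
#' For each time segment, tests the paired condition difference of the
#' segment-mean current at every grid point with a sign-flip permutation
#' test (one synchronized flip vector per rearrangement, shared across grid
#' points), then controls the FDR across grid points within the segment via
#' \code{\link{fdrTwoStage}}.  Reports the corrected threshold p-value per
#' segment (0 when nothing survives).
#'
#' @param srcA,srcB per-subject source estimates for the two conditions:
#'   lists of \code{SourceEstimate}s (same subject order) or
#'   subjects x grid x segments arrays of precomputed segment means.
#' @param segments list of half-open segment windows.
#' @param nRearrangements Monte-Carlo rearrangements.
#' @param q FDR level.
#' @param seed integer seed.
#' @return object of class \code{segmentContrast}: per segment a list with
#'   \code{p} (per-grid p-values), \code{mask} (FDR-rejection mask),
#'   \code{pThr}, \code{meanDiff} (group-mean A - B segment current);
#'   plus \code{pThrTable}.
#' @export
segmentContrastTest <- function(srcA, srcB, segments = segmentWindows(),
                                nRearrangements = 1000, q = 0.05,
                                seed = NULL) {
  A <- .segmentMeanArray(srcA, segments)
  B <- .segmentMeanArray(srcB, segments)
  if (!identical(dim(A), dim(B))) stop("srcA and srcB must match in dimensions")
  n <- dim(A)[1]
  if (n < 2) stop("need at least 2 subjects")
  nSeg <- dim(A)[3]
  .setSeed(seed)
  res <- vector("list", nSeg)
  names(res) <- dimnames(A)[[3]]
  for (s in seq_len(nSeg)) {
    D <- A[, , s] - B[, , s]              # n x grid
    obs <- colMeans(D)
    flips <- .flipMatrix(nRearrangements, n)
    null <- abs(flips %*% D) / n
    p <- colMeans(sweep(null, 2, abs(obs) - 1e-12, ">="))
    fdr <- fdrTwoStage(p, q = q)
    res[[s]] <- list(p = p, mask = fdr$rejected, pThr = fdr$threshold,
                     meanDiff = obs)
  }
  structure(list(segments = res,
                 pThrTable = vapply(res, `[[`, numeric(1), "pThr"),
                 params = list(nRearrangements = nRearrangements, q = q,
                               windows = segments, seed = seed)),
            class = "segmentContrast")
}

.segmentMeanArray <- function(src, segments) {
  if (is.array(src) && length(dim(src)) == 3) {
    if (is.null(dimnames(src)[[3]])) dimnames(src)[[3]] <- names(segments)
    return(src)
  }
  if (!is.list(src) || !all(vapply(src, is, logical(1), "SourceEstimate"))) {
    stop("srcA/srcB must be lists of SourceEstimate or 3D arrays")
  }
  mats <- lapply(src, sourceSegmentMeans, segments = segments)
  arr <- array(0, c(length(src), nrow(mats[[1]]), length(segments)),
               dimnames = list(NULL, NULL, names(segments)))
  for (i in seq_along(mats)) arr[i, , ] <- mats[[i]]
  arr
}

#' @export
print.segmentContrast <- function(x, ...) {
  cat("Per-segment source contrast (paired sign-flip tests + two-stage FDR)\n")
  cat(sprintf("  q = %.3g, %d rearrangements\n",
              x$params$q, x$params$nRearrangements))
  for (nm in names(x$segments)) {
    s <- x$segments[[nm]]
    cat(sprintf("  %s: %4d significant grid points, p_thr = %.4g\n",
                nm, sum(s$mask), s$pThr))
  }
  invisible(x)
}

#' Region-level report of significant source activity
#'
#' Summarizes a segment contrast over the forward model's region partition.
#' Per region and segment, the "area of significant activation" is the
#' percentage of the region's grid points inside the FDR-rejection mask.
#' A region is reported when its area reaches \code{minArea} percent
#' (inclusive: exactly 10 percent is reported) in at least one segment;
#' the segment list marks each qualifying segment with the sign of the mean
#' condition difference over the significant points, in the style
#' "S1(+), S3(-)".  Activation strength is the mean signed current
#' difference (nominal nAm) over the significant points of the qualifying
#' segments; the peak coordinate is that of the significant point with the
#' largest absolute difference.
#'
#' @param contrast a \code{segmentContrast}.
#' @param fm the \code{\link{ForwardModel-class}} supplying the partition.
#' @param minArea reporting cutoff in percent.
#' @return data.frame with columns \code{region}, \code{x}, \code{y},
#'   \code{z}, \code{area_pct} (maximum over qualifying segments),
#'   \code{strength}, \code{segments}; zero rows when nothing qualifies.
#' @export
regionReport <- function(contrast, fm, minArea = 10) {
  stopifnot(inherits(contrast, "segmentContrast"), is(fm, "ForwardModel"))
  labels <- regionLabels(fm)
  coords <- gridCoords(fm)
  segs <- contrast$segments
  rows <- list()
  for (reg in levels(labels)) {
    gIdx <- which(labels == reg)
    if (!length(gIdx)) next
    segNames <- character(); segSigns <- character()
    area <- 0
    sigAll <- integer(); diffAll <- numeric()
    for (nm in names(segs)) {
      mask <- segs[[nm]]$mask[gIdx]
      a <- 100 * sum(mask) / length(gIdx)
      if (a >= minArea - 1e-9) {
        sig <- gIdx[mask]
        md <- segs[[nm]]$meanDiff[sig]
        segNames <- c(segNames, nm)
        segSigns <- c(segSigns, if (mean(md) >= 0) "+" else "-")
        area <- max(area, a)
        sigAll <- c(sigAll, sig)
        diffAll <- c(diffAll, md)
      }
    }
    if (!length(segNames)) next
    peak <- sigAll[which.max(abs(diffAll))]
    rows[[reg]] <- data.frame(
      region = reg,
      x = coords[peak, 1], y = coords[peak, 2], z = coords[peak, 3],
      area_pct = area,
      strength = mean(diffAll),
      segments = paste0(segNames, "(", segSigns, ")", collapse = ", "),
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(region = character(), x = numeric(), y = numeric(),
               z = numeric(), area_pct = numeric(), strength = numeric(),
               segments = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(-out$area_pct), , drop = FALSE]
}
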
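#' Generate a toy forward model
#'
#' Builds a smooth synthetic leadfield linking source currents at 3D grid
#' points to the planar-gradiometer channels of a layout.  Channel
#' sensitivity falls off with distance as a Gaussian kernel; the split
#' between the horizontal and vertical channel of a pair follows a smoothly
#' varying source orientation field, so leadfield columns vary smoothly over
#' neighbouring grid points and no grid point is invisible.  The grid is
#' partitioned into named regions by k-means clustering of the coordinates.
#' This is deliberately a toy stand-in for a boundary-element forward
#' calculation: adequate for closed-loop inverse testing, not for
#' physiological realism.
#'
#' @param nGrid number of grid points (>= \code{nRegions}).
#' @param layout a \code{\link{SensorLayout-class}}; sensors sit in the
#'   z = 0 plane at their layout coordinates.
#' @param nRegions number of regions in the partition.
#' @param sigma Gaussian kernel width; default half the mean inter-sensor
#'   distance.
#' @param depth range \code{c(zmin, zmax)} of grid depths below the sensor
#'   plane.
#' @param columnNorm "unit" (default) rescales every leadfield column to
#'   unit norm, equalizing grid-point visibility so that the unweighted L2
#'   minimum-norm inverse is identifiable on the toy model; "none" keeps the
#'   raw distance-dependent norms (which bias minimum-norm peaks toward
#'   well-seen points, as with real leadfields lacking depth weighting).
#' @param seed integer seed.
#' @return a \code{\link{ForwardModel-class}}.
#' @examples
#' lay <- generateSensorLayout(9)
#' fm <- generateForward(60, lay, seed = 1)
#' fm
#' @export
generateForward <- function(nGrid, layout, nRegions = 8, sigma = NULL,
                            depth = c(-1.2, -0.3),
                            columnNorm = c("unit", "none"), seed = NULL) {
  columnNorm <- match.arg(columnNorm)
  stopifnot(is(layout, "SensorLayout"))
  .assertScalar(nGrid, "nGrid", lower = nRegions)
  nGrid <- as.integer(nGrid)
  pos <- sensorPositions(layout)
  .setSeed(seed)
  coords <- cbind(
    x = runif(nGrid, min(pos[, 1]) - 0.5, max(pos[, 1]) + 0.5),
    y = runif(nGrid, min(pos[, 2]) - 0.5, max(pos[, 2]) + 0.5),
    z = runif(nGrid, depth[1], depth[2])
  )
  if (is.null(sigma)) sigma <- mean(dist(pos)) / 2
  sens3d <- cbind(pos, z = 0)

  ## smooth orientation and gain fields over the grid
  w1 <- rnorm(3); w2 <- rnorm(3)
  theta <- as.numeric(coords %*% w1)
  gain <- 1 + 0.5 * tanh(as.numeric(coords %*% w2))

  pm <- pairMap(layout)
  chans <- channelNames(layout)
  L <- matrix(0, length(chans), nGrid, dimnames = list(chans, NULL))
  for (p in seq_len(nrow(pos))) {
    d2 <- rowSums(sweep(coords, 2, sens3d[p, ])^2)
    kern <- exp(-d2 / (2 * sigma^2))
    L[pm$hChannel[p], ] <- gain * kern * cos(theta)
    L[pm$vChannel[p], ] <- gain * kern * sin(theta)
  }
  if (max(abs(L)) < 1e-12) stop("degenerate (rank-0) leadfield")
  if (columnNorm == "unit") L <- sweep(L, 2, sqrt(colSums(L^2)), "/")

  km <- kmeans(coords, centers = nRegions, nstart = 5)
  labels <- factor(sprintf("R%02d", km$cluster),
                   levels = sprintf("R%02d", seq_len(nRegions)))

  d <- as.matrix(dist(coords))
  diag(d) <- Inf
  nn <- stats::median(apply(d, 1, min))
  adj <- which(upper.tri(d) & d <= 1.5 * nn, arr.ind = TRUE)
  colnames(adj) <- c("from", "to")

  new("ForwardModel", leadfield = L, gridCoords = coords,
      regionLabels = labels, gridAdjacency = adj)
}

#' Neighbourhood of a grid point
#'
#' Grid points adjacent to \code{g} (including \code{g} itself) under the
#' forward model's grid adjacency; used to score localization accuracy.
#' @param fm a \code{ForwardModel}.
#' @param g grid point index.
#' @return integer vector of grid indices.
#' @export
gridNeighborhood <- function(fm, g) {
  adj <- adjacency(fm)
  sort(unique(c(g, adj[adj[, 1] == g, 2], adj[adj[, 2] == g, 1])))
}

#' Project source time courses to sensors
#'
#' Computes sensor data = leadfield x sources (+ optional white noise),
#' enabling closed-loop tests of the minimum-norm inverse.
#'
#' @param fm a \code{\link{ForwardModel-class}}.
#' @param sources either a grid x time matrix, or a trials x grid x time
#'   array (then an \code{\link{EpochSet-class}} is returned and
#'   \code{times} is required).
#' @param times time axis in seconds (required for array input).
#' @param noiseSd white sensor-noise standard deviation.
#' @param seed integer seed for the noise.
#' @return channels x time matrix, or an \code{EpochSet} for array input.
#' @export
projectSources <- function(fm, sources, times = NULL, noiseSd = 0,
                           seed = NULL) {
  stopifnot(is(fm, "ForwardModel"))
  L <- leadfield(fm)
  .setSeed(seed)
  if (is.matrix(sources)) {
    if (nrow(sources) != ncol(L)) stop("sources rows must match grid points")
    out <- L %*% sources
    if (noiseSd > 0) out <- out + matrix(rnorm(length(out), 0, noiseSd),
                                         nrow(out), ncol(out))
    return(out)
  }
  if (length(dim(sources)) != 3) {
    stop("sources must be a matrix (grid x time) or array (trials x grid x time)")
  }
  if (is.null(times)) stop("times is required for epoch (array) sources")
  nTrial <- dim(sources)[1]
  nT <- dim(sources)[3]
  if (dim(sources)[2] != ncol(L)) stop("sources grid dimension must match leadfield")
  dat <- array(0, c(nTrial, nrow(L), nT))
  for (i in seq_len(nTrial)) {
    x <- L %*% sources[i, , ]
    if (noiseSd > 0) x <- x + matrix(rnorm(length(x), 0, noiseSd), nrow(x), ncol(x))
    dat[i, , ] <- x
  }
  dimnames(dat) <- list(NULL, rownames(L), NULL)
  sf <- if (length(times) > 1) 1 / mean(diff(times)) else 1
  new("EpochSet", data = dat, times = times, sfreq = sf,
      conditions = factor(rep("sim", nTrial)),
      covariates = data.frame(row.names = seq_len(nTrial)),
      subject = NULL, combined = FALSE)
}
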
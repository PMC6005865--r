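#' Generate a toy planar-gradiometer sensor layout
#'
#' Places \code{nPairs} planar-gradiometer pair positions in a 2D layout
#' plane, assigns each position a horizontal and a vertical channel, builds
#' the spatial adjacency graph (positions within \code{threshold} of each
#' other), and labels named sensor groups (by layout rows: "frontal",
#' "central", "temporal", "posterior") that the generator can target with
#' planted effects.
#'
#' @param nPairs number of pair positions (>= 4).
#' @param geometry "grid" (near-square lattice with unit step), "circle"
#'   (unit-radius ring) or "random" (uniform in the unit square).
#' @param threshold adjacency distance threshold (inclusive).  Default: 1.1
#'   lattice steps for "grid", otherwise 1.5 times the median
#'   nearest-neighbour distance.
#' @param seed seed used by the "random" geometry.
#' @return a \code{\link{SensorLayout-class}} object.
#' @examples
#' lay <- generateSensorLayout(16)
#' lay
#' @export
generateSensorLayout <- function(nPairs,
                                 geometry = c("grid", "circle", "random"),
                                 threshold = NULL, seed = NULL) {
  geometry <- match.arg(geometry)
  .assertScalar(nPairs, "nPairs", lower = 4)
  nPairs <- as.integer(nPairs)
  pos <- switch(geometry,
    grid = {
      ncols <- ceiling(sqrt(nPairs))
      nrows <- ceiling(nPairs / ncols)
      g <- expand.grid(x = seq_len(ncols) - 1, y = seq_len(nrows) - 1)
      as.matrix(g[seq_len(nPairs), c("x", "y")])
    },
    circle = {
      th <- 2 * pi * (seq_len(nPairs) - 1) / nPairs
      cbind(x = cos(th), y = sin(th))
    },
    random = {
      .setSeed(seed)
      cbind(x = runif(nPairs), y = runif(nPairs))
    }
  )
  rownames(pos) <- sprintf("P%02d", seq_len(nPairs))
  d <- as.matrix(dist(pos))
  diag(d) <- Inf
  if (any(d < 1e-9)) stop("degenerate geometry: coincident sensor positions")
  if (is.null(threshold)) {
    threshold <- if (geometry == "grid") 1.1 else 1.5 * stats::median(apply(d, 1, min))
  }
  adj <- which(upper.tri(d) & d <= threshold + 1e-12, arr.ind = TRUE)
  dimnames(adj) <- list(NULL, c("from", "to"))
  pm <- data.frame(
    position = rownames(pos),
    hChannel = paste0(rownames(pos), "_h"),
    vChannel = paste0(rownames(pos), "_v"),
    stringsAsFactors = FALSE
  )
  ## groups by vertical (y) quartile of the layout, front at the top
  yq <- cut(rank(pos[, "y"], ties.method = "first"),
            breaks = 4, labels = FALSE)
  groups <- list(
    posterior = which(yq == 1L),
    temporal  = which(yq == 2L),
    central   = which(yq == 3L),
    frontal   = which(yq == 4L)
  )
  new("SensorLayout", positions = pos, pairMap = pm,
      adjacency = adj, threshold = threshold, groups = groups)
}

#' All channel names of a layout (h and v interleaved by position)
#' @param layout a \code{SensorLayout}.
#' @return character vector of channel names.
#' @export
channelNames <- function(layout) {
  pm <- pairMap(layout)
  as.vector(rbind(pm$hChannel, pm$vChannel))
}
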
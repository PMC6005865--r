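#' Probability of superiority for dependent samples (PS_dep)
#'
#' Nonparametric paired effect size: the probability that in a randomly
#' sampled matched pair the value from the second condition exceeds the
#' first, PS_dep = Pr(y_i > x_i).  Ties contribute 0.5, so
#' \code{psDep(x, x) == 0.5} and \code{psDep(x, y) == 1 - psDep(y, x)}.
#'
#' @param x,y paired numeric vectors of equal length >= 1.
#' @return a probability in [0, 1].
#' @examples
#' psDep(1:5, 1:5 + 1)   # 1
#' psDep(1:5, 1:5)       # 0.5
#' @export
psDep <- function(x, y) {
  if (length(x) != length(y) || length(x) < 1) {
    stop("x and y must be paired vectors of equal length >= 1")
  }
  if (anyNA(x) || anyNA(y)) stop("NA values not allowed")
  (sum(y > x) + 0.5 * sum(y == x)) / length(x)
}

#' Paired Monte-Carlo permutation test
#'
#' Tests a paired difference across subjects by random sign flips of the
#' per-subject differences.  The test statistic is the difference in sample
#' means, mean(x) - mean(y); the two-sided p-value is the plain proportion
#' of resampled statistics whose absolute value is at least the observed
#' one.  The PS_dep effect size (\code{\link{psDep}}) is attached.
#'
#' @param x,y per-subject paired values (equal length >= 2, no NA).
#' @param nRearrangements number of random sign-flip rearrangements.
#' @param seed integer seed for reproducibility.
#' @param addOne if TRUE, use the (1 + b)/(1 + B) correction so reported
#'   p-values cannot be exactly zero.  Default FALSE (plain proportion).
#' @return object of class \code{permTest}: \code{statistic},
#'   \code{p.value}, \code{psDep}, \code{null} (resampled statistics),
#'   \code{nRearrangements}, \code{n}, \code{seed}.
#' @examples
#' set.seed(1)
#' x <- rnorm(12); y <- x + rnorm(12, 0.8, 0.5)
#' pairedPermutationTest(x, y, nRearrangements = 2000, seed = 1)
#' @export
pairedPermutationTest <- function(x, y, nRearrangements = 5000, seed = NULL,
                                  addOne = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 2) stop("need at least 2 subjects")
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y)))) {
    stop("NA/NaN/Inf values not allowed")
  }
  d <- x - y
  obs <- mean(d)
  .setSeed(seed)
  flips <- .flipMatrix(nRearrangements, n)
  null <- as.numeric(flips %*% d) / n
  hits <- sum(abs(null) >= abs(obs) - 1e-12)
  p <- if (addOne) (1 + hits) / (1 + nRearrangements) else hits / nRearrangements
  structure(list(statistic = obs, p.value = p, psDep = psDep(x, y),
                 null = null, nRearrangements = nRearrangements,
                 n = n, seed = seed),
            class = "permTest")
}

#' @export
print.permTest <- function(x, ...) {
  cat("Paired Monte-Carlo permutation test (sign flips)\n")
  cat(sprintf("  mean difference = %.4g, p = %.4g (%d rearrangements, n = %d)\n",
              x$statistic, x$p.value, x$nRearrangements, x$n))
  cat(sprintf("  PS_dep = %.3f\n", x$psDep))
  invisible(x)
}

#' Synchronized-rearrangement 2x2 factorial permutation test
#'
#' Nonparametric within-subject 2x2 factorial analysis.  Each effect is
#' carried by its orthogonal per-subject contrast -- main effect A:
#' (mean of A1 cells) - (mean of A2 cells); main effect B likewise;
#' interaction: y11 - y12 - y21 + y22 -- and tested by synchronized sign
#' flips across subjects (one flip per subject per effect, applied to the
#' whole subject's contrast at once).  For a balanced within-subject design
#' each contrast is symmetric about zero under its own null, making the
#' sign-flip distribution exact.  Statistic: mean contrast; two-sided
#' p-values as in \code{\link{pairedPermutationTest}}.
#'
#' @param cells numeric matrix, subjects x 4, columns ordered
#'   (A1B1, A1B2, A2B1, A2B2); for the feedback-by-position design use
#'   \code{\link{conditionCells}} with columns (NF-Bo, NF-In, AF-Bo, AF-In),
#'   i.e. A = feedback, B = ordinal position.
#' @param nRearrangements,seed,addOne as in
#'   \code{\link{pairedPermutationTest}}.
#' @return object of class \code{factorialPermTest} with elements
#'   \code{observed} (named contrasts A, B, AB), \code{p.values} (named),
#'   \code{nRearrangements}, \code{n}, \code{seed}.
#' @export
factorialPermutationTest <- function(cells, nRearrangements = 5000,
                                     seed = NULL, addOne = FALSE) {
  cells <- as.matrix(cells)
  if (ncol(cells) != 4) stop("cells must be a subjects x 4 matrix")
  if (nrow(cells) < 2) stop("need at least 2 subjects with all four cells")
  if (anyNA(cells)) stop("missing cells")
  contr <- cbind(
    A = (cells[, 1] + cells[, 2] - cells[, 3] - cells[, 4]) / 2,
    B = (cells[, 1] - cells[, 2] + cells[, 3] - cells[, 4]) / 2,
    AB = cells[, 1] - cells[, 2] - cells[, 3] + cells[, 4]
  )
  n <- nrow(cells)
  obs <- colMeans(contr)
  .setSeed(seed)
  p <- vapply(c("A", "B", "AB"), function(eff) {
    flips <- .flipMatrix(nRearrangements, n)
    null <- as.numeric(flips %*% contr[, eff]) / n
    hits <- sum(abs(null) >= abs(obs[eff]) - 1e-12)
    if (addOne) (1 + hits) / (1 + nRearrangements) else hits / nRearrangements
  }, numeric(1))
  structure(list(observed = obs, p.values = p,
                 nRearrangements = nRearrangements, n = n, seed = seed),
            class = "factorialPermTest")
}

#' @export
print.factorialPermTest <- function(x, ...) {
  cat("2x2 synchronized-rearrangement factorial permutation test\n")
  cat(sprintf("  n = %d subjects, %d rearrangements per effect\n",
              x$n, x$nRearrangements))
  for (eff in names(x$p.values)) {
    lab <- c(A = "main effect A", B = "main effect B", AB = "interaction")[eff]
    cat(sprintf("  %-13s contrast = %8.4g   p = %.4g\n",
                lab, x$observed[eff], x$p.values[eff]))
  }
  invisible(x)
}

#' Two-stage adaptive linear step-up FDR procedure
#'
#' Controls the false discovery rate at level \code{q} with the adaptive
#' two-stage linear step-up procedure: stage one applies the linear step-up
#' procedure at level q' = q/(1+q); the number of stage-one rejections r1
#' yields the estimate m0 = m - r1 of the number of true nulls; stage two
#' re-applies the linear step-up procedure at level q'·m/m0.  The returned
#' corrected threshold p-value is the largest rejected p-value, reported as
#' 0 when nothing is rejected.
#'
#' @param p vector of p-values in [0, 1].
#' @param q FDR level in (0, 1).
#' @return list with \code{threshold} (corrected threshold p-value),
#'   \code{rejected} (logical mask in input order), \code{r1} (stage-one
#'   rejections) and \code{m0} (estimated true nulls).
#' @examples
#' fdrTwoStage(c(0.001, 0.002, 0.4, 0.8, 0.9), q = 0.05)
#' @export
fdrTwoStage <- function(p, q = 0.05) {
  if (length(q) != 1 || is.na(q) || q <= 0 || q >= 1) stop("q must be in (0, 1)")
  if (anyNA(p) || any(p < 0) || any(p > 1)) stop("p-values must be in [0, 1]")
  m <- length(p)
  q1 <- q / (1 + q)
  r1 <- sum(.stepUp(p, q1))
  if (r1 == 0) {
    return(list(threshold = 0, rejected = rep(FALSE, m), r1 = 0L, m0 = m))
  }
  if (r1 == m) {
    return(list(threshold = max(p), rejected = rep(TRUE, m), r1 = m, m0 = 0L))
  }
  m0 <- m - r1
  rej <- .stepUp(p, q1 * m / m0)
  list(threshold = if (any(rej)) max(p[rej]) else 0,
       rejected = rej, r1 = as.integer(r1), m0 = as.integer(m0))
}

## linear (Benjamini-Hochberg) step-up at level alpha
.stepUp <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= alpha * seq_len(m) / m)
  if (!length(k)) return(rep(FALSE, m))
  p <= ps[max(k)]
}
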
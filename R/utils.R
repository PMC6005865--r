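## Internal helpers.

## Derive a child seed from a top-level seed and a stage offset, staying
## inside 32-bit integer range so set.seed() accepts it.
.childSeed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + offset * 1000003) %% 2147483629)
}

.setSeed <- function(seed) {
  if (!is.null(seed)) set.seed(seed)
  invisible(NULL)
}

## sample() without the length-1 surprise
.sample1 <- function(x, prob = NULL) {
  if (length(x) == 1L) return(x)
  x[sample.int(length(x), 1L, prob = prob)]
}

.assertScalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lower || x > upper) {
    stop(sprintf("'%s' must be a scalar in [%s, %s]", name,
                 format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}

## Half-open window [from, to) on a time axis; returns integer indices.
.windowIndex <- function(times, window) {
  which(times >= window[1] - 1e-9 & times < window[2] - 1e-9)
}

## Column means / sds of signed-flip products, used by permutation kernels:
## given D (n x p) and a flip matrix F (B x n), the permuted mean-difference
## statistics are F %*% D / n.
.flipMatrix <- function(B, n) {
  matrix(sample(c(-1, 1), B * n, replace = TRUE), nrow = B, ncol = n)
}

.conditionLabel <- function(feedback, position) {
  paste(feedback, position, sep = "-")
}

.CONDITIONS <- c("NF-Bo", "NF-In", "AF-Bo", "AF-In")
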
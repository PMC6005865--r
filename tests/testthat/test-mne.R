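test_that("noise covariance: white noise, correlated sensors, direct oracle", {
  set.seed(2)
  x <- matrix(rnorm(6 * 5000, sd = 2), 6, 5000,
              dimnames = list(paste0("c", 1:6), NULL))
  C <- estimateNoiseCovariance(x, epsilon = 0)
  expect_lt(max(abs(C - diag(4, 6))), 0.3)

  ## two perfectly correlated sensors
  z <- rnorm(3000)
  x2 <- rbind(a = z, b = z, c = rnorm(3000))
  C2 <- estimateNoiseCovariance(x2, epsilon = 0)
  expect_equal(C2["a", "b"], C2["a", "a"], tolerance = 1e-10)

  ## matches the direct covariance oracle before loading
  C3 <- estimateNoiseCovariance(x2, epsilon = 0)
  oracle <- stats::cov(t(x2))
  expect_equal(unclass(C3), (oracle + t(oracle)) / 2, tolerance = 1e-12,
               ignore_attr = TRUE)

  ## loading makes it positive definite and warns on short baselines
  expect_warning(C4 <- estimateNoiseCovariance(x2[, 1:3], epsilon = 1e-3),
                 "baseline samples")
  expect_true(all(eigen(C4, symmetric = TRUE, only.values = TRUE)$values > 0))
  expect_error(estimateNoiseCovariance(matrix(0, 3, 0)), "empty")
})

test_that("unregularized minimum-norm solution satisfies the projection identities", {
  lay <- generateSensorLayout(8)
  fm <- generateForward(60, lay, seed = 4)
  L <- leadfield(fm)
  set.seed(5)
  sTrue <- rnorm(60)
  b <- L %*% sTrue
  inv <- buildInverse(fm, noiseCov = diag(nrow(L)), lambda = 0)
  sHat <- sourceCurrents(applyInverse(inv, b))[, 1]

  ## exact data reproduction
  expect_lt(sqrt(sum((L %*% sHat - b)^2)) / sqrt(sum(b^2)), 1e-8)
  ## pseudoinverse oracle via SVD
  sv <- svd(L)
  keep <- sv$d > max(dim(L)) * .Machine$double.eps * max(sv$d)
  pinvL <- sv$v[, keep] %*% (t(sv$u[, keep]) / sv$d[keep])
  expect_equal(sHat, as.numeric(pinvL %*% b), tolerance = 1e-8)
  ## minimal norm among exact solutions: adding any null-space component
  ## only increases the norm
  nullv <- sv$v[, !keep, drop = FALSE]
  if (ncol(nullv)) {
    alt <- sHat + nullv %*% rnorm(ncol(nullv))
    expect_gt(sum(alt^2), sum(sHat^2))
  }
  ## and sHat itself is orthogonal to the null space
  if (ncol(nullv)) expect_lt(max(abs(t(nullv) %*% sHat)), 1e-8)

  ## b = 0 -> s = 0, and linearity
  expect_true(all(sourceCurrents(applyInverse(inv, b * 0)) == 0))
  b2 <- matrix(rnorm(nrow(L) * 3), nrow(L))
  s1 <- sourceCurrents(applyInverse(inv, b2))
  s2 <- sourceCurrents(applyInverse(inv, 2 * b2[, 1] + b2[, 2]))
  expect_equal(s2[, 1], 2 * s1[, 1] + s1[, 2], tolerance = 1e-9)
})

test_that("source norm is non-increasing in lambda", {
  lay <- generateSensorLayout(8)
  fm <- generateForward(50, lay, seed = 6)
  set.seed(7)
  b <- leadfield(fm) %*% rnorm(50) + rnorm(16, sd = 0.1)
  norms <- vapply(c(0.01, 0.05, 0.1, 0.5, 1, 5), function(lam) {
    inv <- buildInverse(fm, lambda = lam)
    sqrt(sum(sourceCurrents(applyInverse(inv, b))^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-10))
})

test_that("planted source localizes within the grid neighbourhood at working SNR", {
  lay <- generateSensorLayout(25)
  fm <- generateForward(80, lay, seed = 8)
  L <- leadfield(fm)
  inv <- buildInverse(fm, snr = 3)
  set.seed(9)
  hits <- 0L
  nRuns <- 60
  for (r in seq_len(nRuns)) {
    g <- sample(80, 1)
    b <- L[, g] * 5 + rnorm(nrow(L), sd = 0.05 * max(abs(L[, g])) * 5)
    sHat <- abs(sourceCurrents(applyInverse(inv, b))[, 1])
    if (which.max(sHat) %in% gridNeighborhood(fm, g)) hits <- hits + 1L
  }
  expect_gte(hits / nRuns, 0.8)
})

test_that("segment windows tile the analysis interval and means are exact", {
  sw <- segmentWindows()
  expect_equal(sw$S1, c(0.150, 0.205))
  expect_equal(sw$S4, c(0.315, 0.370))
  expect_equal(sw$S2[1], sw$S1[2])
  expect_equal(sw$S3[1], sw$S2[2])

  times <- seq(0, 0.5, by = 0.005)
  cur <- matrix(rep(seq_along(times), each = 3), 3)
  est <- new("SourceEstimate", currents = cur, times = times)
  sm <- sourceSegmentMeans(est)
  idx <- which(times >= 0.15 & times < 0.205 - 1e-9)
  expect_equal(unname(sm[, "S1"]), rep(mean(idx), 3))
  expect_error(sourceSegmentMeans(
    new("SourceEstimate", currents = cur, times = times + 1)), "outside")
})

test_that("segment contrasts: null yields empty masks with p_thr 0, planted effect localizes in its segment", {
  set.seed(10)
  n <- 10; G <- 60
  ## identical conditions: nothing survives anywhere
  A <- array(rnorm(n * G * 4), c(n, G, 4),
             dimnames = list(NULL, NULL, paste0("S", 1:4)))
  sc0 <- segmentContrastTest(A, A, nRearrangements = 300, seed = 1)
  expect_true(all(vapply(sc0$segments, function(s) sum(s$mask), numeric(1)) == 0))
  expect_true(all(sc0$pThrTable == 0))

  ## effect planted in S3 only, inside one region
  lay <- generateSensorLayout(8)
  fm <- generateForward(G, lay, nRegions = 4, seed = 11)
  reg <- which(regionLabels(fm) == "R02")
  B <- array(rnorm(n * G * 4, sd = 0.3), c(n, G, 4),
             dimnames = list(NULL, NULL, paste0("S", 1:4)))
  A2 <- array(rnorm(n * G * 4, sd = 0.3), c(n, G, 4),
              dimnames = list(NULL, NULL, paste0("S", 1:4)))
  A2[, reg, 3] <- A2[, reg, 3] + 2
  sc <- segmentContrastTest(A2, B, nRearrangements = 500, seed = 2)
  expect_gte(sum(sc$segments$S3$mask[reg]), 0.8 * length(reg))
  expect_equal(sum(sc$segments$S1$mask), 0)
  expect_equal(sum(sc$segments$S2$mask), 0)
  ## corrected threshold equals the largest rejected p-value
  expect_equal(unname(sc$pThrTable["S3"]),
               max(sc$segments$S3$p[sc$segments$S3$mask]))
  expect_equal(unname(sc$pThrTable["S1"]), 0)

  rep <- regionReport(sc, fm)
  expect_true("R02" %in% rep$region)
  expect_match(rep$segments[rep$region == "R02"], "S3\\(\\+\\)")
})

test_that("region report: counting oracle, 10 percent inclusion rule, omission", {
  lay <- generateSensorLayout(8)
  fm <- generateForward(40, lay, nRegions = 4, seed = 12)
  labels <- regionLabels(fm)
  ## synthesize a contrast result with a hand-built mask
  reg1 <- which(labels == levels(labels)[1])
  nSig <- max(1L, round(0.10 * length(reg1)))   # exactly 10 percent when divisible
  mask <- rep(FALSE, 40); mask[reg1[seq_len(nSig)]] <- TRUE
  segs <- list(S1 = list(p = runif(40), mask = mask, pThr = 0.01,
                         meanDiff = rep(1, 40)),
               S2 = list(p = runif(40), mask = rep(FALSE, 40), pThr = 0,
                         meanDiff = rep(1, 40)))
  sc <- structure(list(segments = segs,
                       pThrTable = c(S1 = 0.01, S2 = 0),
                       params = list(q = 0.05, nRearrangements = 100,
                                     windows = segmentWindows(n = 2),
                                     seed = 1)),
                  class = "segmentContrast")
  rep <- regionReport(sc, fm, minArea = 100 * nSig / length(reg1))
  expect_true(levels(labels)[1] %in% rep$region)
  ## area strictly below the cutoff is omitted
  rep2 <- regionReport(sc, fm, minArea = 100 * nSig / length(reg1) + 1)
  expect_false(levels(labels)[1] %in% rep2$region)
  ## zero significant points anywhere -> empty report
  segs0 <- lapply(segs, function(s) { s$mask <- rep(FALSE, 40); s })
  sc0 <- structure(list(segments = segs0, pThrTable = c(S1 = 0, S2 = 0),
                        params = sc$params), class = "segmentContrast")
  expect_equal(nrow(regionReport(sc0, fm)), 0)
  ## area percentage equals the brute-force count ratio
  got <- rep$area_pct[rep$region == levels(labels)[1]]
  expect_equal(got, 100 * sum(mask[reg1]) / length(reg1))
})
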
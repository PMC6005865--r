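test_that("band-pass filter: passband, DC removal, stopband attenuation", {
  sfreq <- 500
  t <- seq(0, 10, by = 1 / sfreq)
  sin10 <- sin(2 * pi * 10 * t)
  x <- rbind(a = sin10)
  y <- bandpassFilter(x, 1, 100, sfreq = sfreq)
  core <- 1000:4000   # avoid edge transients
  amp <- (max(y[1, core]) - min(y[1, core])) / 2
  expect_lt(abs(amp - 1), 0.05)

  dc <- rbind(a = rep(5, length(t)))
  ydc <- bandpassFilter(dc, 1, 100, sfreq = sfreq)
  expect_lt(mean(abs(ydc[1, core])), 0.05)

  ## 0.1 Hz attenuated by >= 20 dB relative to 10 Hz (FFT oracle)
  mix <- rbind(a = sin(2 * pi * 0.1 * t) + sin10)
  ym <- bandpassFilter(mix, 1, 100, sfreq = sfreq)
  sp <- Mod(stats::fft(ym[1, ]))[seq_along(t)]
  freqs <- (seq_along(t) - 1) / length(t) * sfreq
  a01 <- max(sp[abs(freqs - 0.1) < 0.05])
  a10 <- max(sp[abs(freqs - 10) < 0.05])
  expect_gt(20 * log10(a10 / a01), 20)

  expect_error(bandpassFilter(x, 100, 1, sfreq = sfreq), "band edges")
  expect_error(bandpassFilter(x, 1, 400, sfreq = sfreq), "band edges")
})

mkRecording <- function(nCh = 4, durMs = 8000, sfreq = 500, trigs = c(3000, 5000),
                        delay = 22.5, data = NULL) {
  n <- ceiling(durMs / 1000 * sfreq)
  if (is.null(data)) data <- matrix(0, nCh, n)
  rownames(data) <- paste0("P", sprintf("%02d", rep(1:(nCh / 2), each = 2)),
                           c("_h", "_v"))
  trg <- data.frame(time_ms = trigs + delay, block = 1L, trial = 1L,
                    keystroke = seq_along(trigs),
                    feedback = "NF", position_class = "Bo",
                    seq_position = 1L, is_error = FALSE, velocity = 64,
                    preceding_ioi = 300, gt_post_af = 0L)
  new("ContinuousRecording", data = data, sfreq = sfreq, triggers = trg,
      baselineIntervals = matrix(c(0, 1000), 1), subject = "S01")
}

test_that("epoching corrects the trigger latency so t = 0 is the keystroke", {
  sfreq <- 500
  rec <- mkRecording(sfreq = sfreq)
  d <- recordingData(rec)
  ## impulse exactly at the keystroke sample of the first trigger
  ks <- round(3000 / 1000 * sfreq) + 1
  d[1, ks] <- 1
  rec@data <- d
  ep <- epochRecording(rec, latencyCorrection = 22.5, window = c(-1, 1))
  t0 <- which(abs(epochTimes(ep)) < 1e-12)
  expect_equal(unname(epochData(ep)[1, 1, t0]), 1)
  expect_equal(sum(epochData(ep)[1, 1, ] != 0), 1)

  ## a trigger too close to the recording end is dropped
  rec2 <- mkRecording(trigs = c(3000, 7600))
  expect_message(ep2 <- epochRecording(rec2, 22.5), "dropped")
  expect_equal(dim(ep2)[1], 1L)

  expect_error(epochRecording(mkRecording(trigs = 7990), 22.5), "no valid")

  ## correction 0 vs 22.5 ms shifts waveforms by round(22.5 ms * sfreq)
  set.seed(8)
  rec3 <- mkRecording(data = matrix(rnorm(4 * 4000), 4))
  epA <- epochRecording(rec3, latencyCorrection = 0, window = c(-0.5, 0.5))
  epB <- epochRecording(rec3, latencyCorrection = 22.5, window = c(-0.5, 0.5))
  shift <- round(22.5 / 1000 * 500)
  xa <- epochData(epA)[1, 1, ]
  xb <- epochData(epB)[1, 1, ]
  nT <- length(xa)
  expect_equal(xb[(shift + 1):nT], xa[1:(nT - shift)])
})

test_that("baseline correction zeroes the baseline window mean", {
  set.seed(4)
  rec <- mkRecording(data = matrix(rnorm(4 * 4000, mean = 3), 4))
  ep <- epochRecording(rec, 22.5)
  ep <- baselineCorrect(ep, c(-0.2, -0.1))
  idx <- which(epochTimes(ep) >= -0.2 & epochTimes(ep) < -0.1 - 1e-9)
  for (tr in seq_len(dim(ep)[1])) {
    for (ch in seq_len(dim(ep)[2])) {
      expect_lt(abs(mean(epochData(ep)[tr, ch, idx])), 1e-10)
    }
  }
  expect_error(baselineCorrect(ep, c(-2, -1.9)), "inside the epoch")
})

test_that("planar combination: Pythagoras, zero case, oracle, non-negativity", {
  lay <- generateSensorLayout(4)
  m <- matrix(c(3, 4, 0, 0, 1, 1, 2, 2), 8, 3,
              dimnames = list(channelNames(lay), NULL))
  cp <- combinePlanar(m, lay)
  expect_equal(cp["P01", ], rep(5, 3))
  expect_equal(cp["P02", ], rep(0, 3))
  expect_true(all(cp >= 0))

  set.seed(6)
  r <- matrix(rnorm(8 * 10), 8, 10, dimnames = list(channelNames(lay), NULL))
  cp2 <- combinePlanar(r, lay)
  for (p in 1:4) {
    expect_equal(cp2[p, ], sqrt(r[2 * p - 1, ]^2 + r[2 * p, ]^2),
                 ignore_attr = TRUE)
  }
  cp3 <- combinePlanar(r, lay, scheme = "rms")
  expect_equal(cp3, cp2 / sqrt(2))

  rownames(r)[2] <- "XX"
  expect_error(combinePlanar(r, lay), "unpaired")
})

test_that("condition averaging equals the two-pass mean and flags empties", {
  set.seed(11)
  dat <- array(rnorm(6 * 4 * 10), c(6, 4, 10))
  ep <- new("EpochSet", data = dat, times = seq(-0.5, 0.4, by = 0.1),
            sfreq = 10,
            conditions = factor(rep(c("AF-Bo", "NF-Bo"), each = 3),
                                levels = c("AF-Bo", "NF-Bo")),
            covariates = data.frame(row.names = 1:6), subject = "S01",
            combined = FALSE)
  avg <- conditionAverage(ep)
  manual <- matrix(0, 4, 10)
  for (i in 1:3) manual <- manual + dat[i, , ] / 3
  expect_equal(avg[["AF-Bo"]], manual)
  expect_equal(unname(attr(avg, "counts")), c(3L, 3L))
  ## +v and -v trials average to zero
  dat2 <- dat; dat2[2, , ] <- -dat2[1, , ]; dat2[3, , ] <- 0
  ep@data <- dat2
  expect_equal(max(abs(conditionAverage(ep)[["AF-Bo"]])), 0)
  expect_error(conditionAverage(ep, which = "AF-In"), "empty condition")
})

mkTriggerTable <- function(n = 60, pAf = 0.2, seed = 1) {
  set.seed(seed)
  fb <- ifelse(runif(n) < pAf, "AF", "NF")
  data.frame(time_ms = seq(1000, by = 300, length.out = n),
             block = 1L, trial = 1L, keystroke = seq_len(n),
             feedback = fb,
             position_class = sample(c("Bo", "In"), n, replace = TRUE),
             seq_position = 1L, is_error = FALSE,
             velocity = rnorm(n, 64, 8),
             preceding_ioi = c(NA, runif(n - 1, 250, 350)),
             stringsAsFactors = FALSE)
}

test_that("matched-control selection: counts, exclusions and balance", {
  trg <- mkTriggerTable(n = 120, seed = 3)
  ## balance warnings are advisory; this random pool happens to drift
  mc <- suppressWarnings(selectMatchedControls(trg))
  for (cl in names(mc$af)) {
    expect_equal(length(mc$nf[[cl]]), length(mc$af[[cl]]))
    expect_true(all(trg$feedback[mc$nf[[cl]]] == "NF"))
    expect_true(all(trg$position_class[mc$nf[[cl]]] == cl))
  }
  ## NF events at +1/+2 after an AF event are never selected
  af <- which(trg$feedback == "AF")
  banned <- intersect(c(af + 1, af + 2), seq_len(nrow(trg)))
  banned <- banned[trg$feedback[banned] == "NF"]
  expect_equal(length(intersect(unlist(mc$nf), banned)), 0L)

  ## pool exhaustion errors
  trgBad <- mkTriggerTable(n = 20, pAf = 0.9, seed = 4)
  expect_error(selectMatchedControls(trgBad), "exhausted")
})

test_that("greedy matching stays near the optimal assignment on small pools", {
  set.seed(21)
  total <- function(zt, zp, assign) {
    sum(sqrt(rowSums((zp[assign, , drop = FALSE] - zt)^2)))
  }
  ratios <- numeric(50)
  for (r in 1:50) {
    zt <- matrix(rnorm(3 * 2), 3, 2)
    zp <- matrix(rnorm(8 * 2), 8, 2)
    greedy <- afmeg:::.greedyMatch(zt, zp)
    best <- Inf
    for (cmb in utils::combn(8, 3, simplify = FALSE)) {
      perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                    c(3, 1, 2), c(3, 2, 1))
      for (pp in perms) best <- min(best, total(zt, zp, cmb[pp]))
    }
    ratios[r] <- total(zt, zp, greedy) / best
  }
  expect_lt(mean(ratios), 1.10)
})

test_that("planted evoked contrast survives the full sensor pipeline", {
  cfg <- tinyConfig(nSubjects = 1, trialsPerBlock = 6, trialDuration = 15,
                    sfreq = 200, noiseAr = 0.8, noiseSd = 0.5,
                    erfEffects = list(erfEffect(feedback = "AF",
                                                group = "frontal",
                                                window = c(0.2, 0.3),
                                                amplitude = 6)),
                    seed = 77)
  lay <- generateSensorLayout(8)
  rec <- generateRecordings(generatePerformance(cfg), lay, cfg)[[1]]
  mc <- selectMatchedControls(triggers(rec))
  sel <- sort(unlist(c(mc$af, mc$nf), use.names = FALSE))
  ep <- baselineCorrect(epochRecording(rec, cfg$midiTriggerDelay, select = sel))
  avg <- conditionAverage(ep)
  afC <- combinePlanar((avg[["AF-Bo"]] + avg[["AF-In"]]) / 2, lay)
  nfC <- combinePlanar((avg[["NF-Bo"]] + avg[["NF-In"]]) / 2, lay)
  contrast <- afC - nfC
  tIdx <- which(epochTimes(ep) >= 0.2 & epochTimes(ep) < 0.3)
  template <- 6 * sin(pi * (seq_along(tIdx) - 0.5) / length(tIdx))
  planted <- sensorGroups(lay)$frontal
  for (p in planted) {
    expect_gt(cor(contrast[p, tIdx], template), 0.9)
  }
  ## non-planted groups carry no systematic contrast of that size
  others <- setdiff(seq_len(8), planted)
  expect_lt(max(abs(contrast[others, tIdx])), max(template) / 2)
})
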
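test_that("config validation enforces the paradigm's structural invariants", {
  expect_error(simulationConfig(afSpacing = c(1, 10)), "afSpacing")
  expect_error(simulationConfig(afSpacing = c(10, 8)), "afSpacing")
  expect_error(simulationConfig(sequencePatterns = list(1:3)), "length 4 or 5")
  expect_error(simulationConfig(baselineErrorProb = 1.5), "baselineErrorProb")
  expect_error(simulationConfig(midiTriggerDelay = 30), "midiTriggerDelay")
  expect_error(simulationConfig(trialDuration = 0), "trialDuration")
  ## AF cannot be placed when the spacing exceeds the trial length
  expect_error(generatePerformance(
    simulationConfig(nSubjects = 1, trialDuration = 1, afFreeTrials = integer())),
    "spacing exceeds")
})

test_that("noiseless null config yields exact nominal IOIs and no events", {
  cfg <- tinyConfig(ioiNoiseSd = 0, baselineErrorProb = 0,
                    errorBoost = c(Bo = 0, In = 0),
                    slowingEffect = c(Bo = 0, In = 0))
  ev <- computeIOI(generatePerformance(cfg))
  expect_true(all(abs(ev$ioi[!is.na(ev$ioi)] - 300) < 1e-9))
  expect_false(any(ev$is_error))
})

test_that("AF placement respects spacing bounds, free trials and class alternation", {
  cfg <- tinyConfig(nSubjects = 4, trialsPerBlock = 8, trialDuration = 20,
                    afFreeTrials = c(1, 6))
  ev <- generatePerformance(cfg)
  sp <- ev$gt_af_spacing[!is.na(ev$gt_af_spacing)]
  expect_true(all(sp %in% 8:10))
  expect_equal(sum(ev$feedback == "AF" & ev$trial %in% c(1, 6)), 0)
  ## every within-trial gap between consecutive AF keystrokes is the
  ## recorded spacing
  for (key in split(seq_len(nrow(ev)), interaction(ev$subject, ev$block, ev$trial))) {
    afk <- ev$keystroke[key][ev$feedback[key] == "AF"]
    if (length(afk) >= 2) expect_true(all(diff(sort(afk)) %in% 8:10))
  }
  ## Bo labels consistent with sequence positions
  patLen <- lengths(cfg$sequencePatterns)
  expect_silent(validateEventTable(ev, patternLengths = stats::setNames(
    patLen, seq_along(patLen))))
})

test_that("generator is bit-reproducible for identical config and seed", {
  cfg <- tinyConfig(seed = 99)
  expect_identical(generatePerformance(cfg), generatePerformance(cfg))
  lay <- generateSensorLayout(6)
  ev <- generatePerformance(tinyConfig(nSubjects = 1, seed = 5))
  r1 <- generateRecordings(ev, lay, tinyConfig(nSubjects = 1, seed = 5))
  r2 <- generateRecordings(ev, lay, tinyConfig(nSubjects = 1, seed = 5))
  expect_identical(recordingData(r1[[1]]), recordingData(r2[[1]]))
})

test_that("planted slowing is recovered by brute-force averaging", {
  cfg <- simulationConfig(nSubjects = 4, trialsPerBlock = 10,
                          sequencePatterns = defaultSequencePatterns()[1:2],
                          slowingEffect = c(Bo = 49, In = 0),
                          errorBoost = c(Bo = 0, In = 0),
                          baselineErrorProb = 0, ioiNoiseSd = 20, seed = 17)
  ev <- generatePerformance(cfg)
  ev <- computeIOI(ev)
  ## brute force: mean IOI(+1) - IOI(event) over AF-Bo events
  d <- c()
  for (key in split(seq_len(nrow(ev)), interaction(ev$subject, ev$block, ev$trial))) {
    idx <- key[order(ev$keystroke[key])]
    af <- which(ev$feedback[idx] == "AF" & ev$position_class[idx] == "Bo")
    af <- af[af >= 2 & af + 1 <= length(idx)]
    d <- c(d, ev$ioi[idx][af + 1] - ev$ioi[idx][af])
  }
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - 49), 4 * se)
})

test_that("layout geometry: corners, empty threshold, brute-force adjacency", {
  lay <- generateSensorLayout(4, geometry = "grid", threshold = 1)
  deg <- tabulate(c(adjacency(lay)), nbins = 4)
  expect_equal(deg, rep(2L, 4))

  lay0 <- generateSensorLayout(4, geometry = "grid", threshold = 0)
  expect_equal(nrow(adjacency(lay0)), 0)

  lay30 <- generateSensorLayout(30, geometry = "random", threshold = 0.25,
                                seed = 8)
  pos <- sensorPositions(lay30)
  expected <- list()
  for (i in 1:29) for (j in (i + 1):30) {
    if (sqrt(sum((pos[i, ] - pos[j, ])^2)) <= 0.25) {
      expected[[length(expected) + 1L]] <- c(i, j)
    }
  }
  got <- adjacency(lay30)
  expect_equal(nrow(got), length(expected))
  expect_true(all(vapply(seq_along(expected), function(k)
    any(got[, 1] == expected[[k]][1] & got[, 2] == expected[[k]][2]),
    logical(1))))
})

test_that("noiseless recordings reproduce the planted template exactly", {
  cfg <- tinyConfig(nSubjects = 1, noiseSd = 0, sfreq = 200,
                    baselineErrorProb = 0, errorBoost = c(Bo = 0, In = 0),
                    erfEffects = list(erfEffect(feedback = "AF",
                                                group = "temporal",
                                                window = c(0.26, 0.37),
                                                amplitude = 3)))
  lay <- generateSensorLayout(8)
  rec <- generateRecordings(generatePerformance(cfg), lay, cfg)[[1]]
  ep <- epochRecording(rec, latencyCorrection = cfg$midiTriggerDelay)
  avg <- conditionAverage(ep)
  afMean <- (avg[["AF-Bo"]] + avg[["AF-In"]]) / 2
  nfMean <- (avg[["NF-Bo"]] + avg[["NF-In"]]) / 2
  diffSig <- afMean - nfMean
  tIdx <- which(epochTimes(ep) >= 0.26 & epochTimes(ep) < 0.37)
  bump <- 3 * sin(pi * (seq_along(tIdx) - 0.5) / length(tIdx))
  hChan <- pairMap(lay)$hChannel[sensorGroups(lay)$temporal]
  for (ch in hChan) {
    expect_equal(unname(diffSig[ch, tIdx]), bump, tolerance = 1e-10)
  }
  ## untouched channels stay flat
  vChan <- pairMap(lay)$vChannel[sensorGroups(lay)$temporal]
  expect_true(all(abs(diffSig[vChan, ]) < 1e-10))
})

test_that("noise-only recordings have near-zero mean and the configured AR(1) lag-1 autocorrelation", {
  cfg <- tinyConfig(nSubjects = 1, trialsPerBlock = 2, trialDuration = 20,
                    sfreq = 500, noiseAr = 0.7, noiseSd = 1, seed = 21)
  lay <- generateSensorLayout(4)
  rec <- generateRecordings(generatePerformance(cfg), lay, cfg)[[1]]
  x <- recordingData(rec)[1, ]
  n <- length(x)
  marg <- 1 / sqrt(1 - 0.7^2)           # marginal sd of the AR(1)
  expect_lt(abs(mean(x)), 4 * marg / sqrt(n * (1 - 0.7) / (1 + 0.7)))
  r1 <- cor(x[-1], x[-n])
  se <- sqrt((1 - 0.7^2) / n)
  expect_lt(abs(r1 - 0.7), 4 * se)
})

test_that("effect windows outside the epoch range are rejected", {
  expect_error(erfEffect(feedback = "AF", group = "temporal",
                         window = c(0.9, 1.2), amplitude = 1),
               "epoch range")
  cfg <- tinyConfig(nSubjects = 1)
  cfg$erfEffects <- list(list(feedback = "AF", position = NA,
                              group = "temporal", window = c(-2, 0),
                              amplitude = 1))
  lay <- generateSensorLayout(8)
  expect_error(generateRecordings(generatePerformance(cfg), lay, cfg),
               "epoch range")
})

test_that("forward model is a valid partition and projection is linear", {
  lay <- generateSensorLayout(9)
  fm <- generateForward(40, lay, nRegions = 5, seed = 3)
  L <- leadfield(fm)
  expect_true(all(colSums(abs(L)) > 0))
  expect_equal(length(regionLabels(fm)), 40)
  expect_false(anyNA(regionLabels(fm)))

  ## zero sources -> zero data; single point -> proportional to its column
  expect_true(all(projectSources(fm, matrix(0, 40, 5)) == 0))
  s <- matrix(0, 40, 3); s[7, ] <- c(1, 2, -1)
  expect_equal(projectSources(fm, s), L[, 7, drop = FALSE] %*% t(c(1, 2, -1)),
               ignore_attr = TRUE)
  ## two active points equal the explicit sum of scaled columns
  s2 <- matrix(0, 40, 2); s2[3, ] <- c(2, 0.5); s2[31, ] <- c(-1, 4)
  expect_equal(projectSources(fm, s2),
               L[, 3, drop = FALSE] %*% t(c(2, 0.5)) +
                 L[, 31, drop = FALSE] %*% t(c(-1, 4)),
               ignore_attr = TRUE)
  expect_error(generateForward(3, lay, nRegions = 8), "nGrid")
})
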
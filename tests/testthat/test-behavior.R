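mkTrial <- function(onsets, feedback = NULL, errors = NULL, cls = NULL,
                    subject = 1, trial = 1) {
  n <- length(onsets)
  pos <- rep_len(1:4, n)
  data.frame(subject = subject, block = 1L, trial = trial,
             keystroke = seq_len(n), onset_ms = onsets,
             pitch_played = 60L + pos, pitch_heard = 60L + pos,
             velocity = 64, seq_position = pos,
             position_class = if (is.null(cls))
               ifelse(pos %in% c(1, 4), "Bo", "In") else cls,
             feedback = if (is.null(feedback)) rep("NF", n) else feedback,
             is_error = if (is.null(errors)) rep(FALSE, n) else errors,
             stringsAsFactors = FALSE)
}

test_that("IOI and cvIOI arithmetic and oracle equivalence", {
  ev <- computeIOI(mkTrial(c(0, 300, 600, 900)))
  expect_equal(ev$ioi, c(NA, 300, 300, 300))
  expect_equal(computeCvIOI(ev)$cv_ioi, 0)

  ev2 <- computeIOI(mkTrial(c(0, 300, 650)))
  expect_equal(ev2$ioi, c(NA, 300, 350))

  set.seed(1)
  onsets <- cumsum(c(0, runif(49, 150, 450)))
  cv <- computeCvIOI(mkTrial(onsets))$cv_ioi
  expect_equal(cv, oracleCvIOI(onsets), tolerance = 1e-12)

  bad <- mkTrial(c(0, 300, 250, 600))
  expect_error(computeIOI(bad), "non-monotonic.*1/1/1")
})

test_that("IOIs are never computed across trial borders", {
  ev <- rbind(mkTrial(c(0, 300, 600), trial = 1),
              mkTrial(c(0, 310, 620), trial = 2))
  out <- computeIOI(ev)
  expect_equal(sum(is.na(out$ioi)), 2)
  expect_equal(out$ioi[out$trial == 2], c(NA, 310, 310))
})

test_that("windowed error rate: direct counts and exclusion rule", {
  ## 10 AF events, no errors anywhere -> rate 0
  fb <- rep(c("AF", rep("NF", 9)), 10)
  ev <- mkTrial(seq(0, by = 300, length.out = length(fb)), feedback = fb)
  er <- computeErrorRate(ev)
  expect_equal(er$rate[er$feedback == "AF"], c(0, 0))

  ## 4 eligible AF events, exactly one followed by an error at +3 -> 0.25
  n <- 40
  fb <- rep("NF", n); fb[c(5, 15, 25, 35)] <- "AF"
  errs <- rep(FALSE, n); errs[18] <- TRUE
  ev <- mkTrial(seq(0, by = 300, length.out = n), feedback = fb,
                errors = errs, cls = rep("In", n))
  er <- computeErrorRate(ev)
  afRow <- er[er$feedback == "AF" & er$position_class == "In", ]
  expect_equal(afRow$n_events, 4L)
  expect_equal(afRow$rate, 0.25)

  ## AF event B four keystrokes after AF event A, error at A+2:
  ## A is excluded, so the error does not count against any AF event
  n <- 30
  fb <- rep("NF", n); fb[c(10, 14)] <- "AF"
  errs <- rep(FALSE, n); errs[12] <- TRUE
  ev <- mkTrial(seq(0, by = 300, length.out = n), feedback = fb,
                errors = errs, cls = rep("In", n))
  er <- computeErrorRate(ev)
  afRow <- er[er$feedback == "AF" & er$position_class == "In", ]
  expect_equal(afRow$n_events, 1L)   # only B survives the exclusion
  expect_equal(afRow$rate, 0)
})

test_that("error rate and delta-IOI match brute-force oracles on random tables", {
  set.seed(101)
  for (rep in 1:12) {
    ev <- randomEventTable()
    er <- suppressWarnings(computeErrorRate(ev))
    orc <- oracleErrorRate(ev)
    m <- merge(er, orc, by = c("subject", "feedback", "position_class"))
    expect_equal(m$n_events.x, m$n_events.y)
    expect_equal(m$rate.x, m$rate.y)

    di <- computePostFeedbackChange(ev)
    od <- oracleDeltaIOI(ev)
    m2 <- merge(di, od, by = c("subject", "feedback", "position_class"))
    expect_gt(nrow(m2), 0)
    expect_equal(m2$mean_dioi.x, m2$mean_dioi.y, tolerance = 1e-12)
  }
})

test_that("delta-IOI arithmetic and invariance under time translation", {
  ## IOI(event)=350, IOI(+1)=399 -> +49
  ev <- mkTrial(c(0, 350, 749, 1049), feedback = c("NF", "AF", "NF", "NF"),
                cls = rep("Bo", 4))
  di <- computePostFeedbackChange(ev)
  expect_equal(di$mean_dioi[di$feedback == "AF"], 49)

  ## constant tempo -> all condition means 0
  fb <- rep("NF", 30); fb[c(9, 18)] <- "AF"
  ev2 <- mkTrial(seq(0, by = 300, length.out = 30), feedback = fb)
  di2 <- computePostFeedbackChange(ev2)
  expect_true(all(abs(di2$mean_dioi) < 1e-9))

  ## uniform time translation of a trial leaves delta-IOI unchanged
  set.seed(7)
  ev3 <- randomEventTable(nSubj = 1)
  ev4 <- ev3
  ev4$onset_ms <- ev4$onset_ms + 5000
  expect_equal(computePostFeedbackChange(ev3)$mean_dioi,
               computePostFeedbackChange(ev4)$mean_dioi)

  ## trial reordering leaves rates unchanged
  ev5 <- ev3[order(-ev3$trial, ev3$keystroke), ]
  e1 <- computeErrorRate(ev3); e2 <- computeErrorRate(ev5)
  expect_equal(e1$rate, e2$rate)
})

test_that("generated slowing effects are recovered per condition", {
  cfg <- simulationConfig(nSubjects = 8, trialsPerBlock = 8,
                          sequencePatterns = defaultSequencePatterns()[1:2],
                          slowingEffect = c(Bo = 50, In = 0),
                          errorBoost = c(Bo = 0, In = 0),
                          baselineErrorProb = 0, ioiNoiseSd = 30, seed = 31)
  di <- computePostFeedbackChange(generatePerformance(cfg))
  m <- aggregate(mean_dioi ~ feedback + position_class, di, mean)
  afBo <- m$mean_dioi[m$feedback == "AF" & m$position_class == "Bo"]
  afIn <- m$mean_dioi[m$feedback == "AF" & m$position_class == "In"]
  expect_lt(abs(afBo - 50), 6)
  expect_lt(abs(afIn), 6)
})

test_that("error detection from pitch streams equals the injected mask", {
  cfg <- tinyConfig(baselineErrorProb = 0.1, errorBoost = c(Bo = 0.1, In = 0))
  ev <- generatePerformance(cfg)
  expect_gt(sum(ev$gt_error_injected), 0)
  det <- detectErrors(ev, cfg$sequencePatterns)
  expect_equal(det$is_error, ev$gt_error_injected)

  ## perfect performance -> zero errors; one substitution -> one error
  clean <- mkTrial(seq(0, by = 300, length.out = 12))
  expect_false(any(detectErrors(clean, list(61:64))$is_error))
  clean$pitch_played[5] <- 70L
  expect_equal(which(detectErrors(clean, list(61:64))$is_error), 5L)
  expect_error(detectErrors(transform(clean, block = 9), list(61:64)),
               "unknown pattern")
})

test_that("learning curves on AF-free trials behave as constructed", {
  ## stationary generator: first-vs-last cvIOI difference near zero
  cfg <- simulationConfig(nSubjects = 10, trialsPerBlock = 10,
                          sequencePatterns = defaultSequencePatterns()[1:2],
                          afFreeTrials = c(1, 6, 10), ioiNoiseSd = 60,
                          seed = 13)
  lc <- learningCurves(generatePerformance(cfg), afFreeTrials = c(1, 6, 10))
  d <- lc$cvPairs$last - lc$cvPairs$first
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)) + 0.02)
  expect_true(all(c("firstHalf", "secondHalf") %in% names(lc$halfPairs)))

  ## a single AF-free trial cannot support a first-vs-last comparison
  expect_error(learningCurves(generatePerformance(tinyConfig()),
                              afFreeTrials = 1), "at least two")
})

test_that("condition cells reshape preserves values and ordering", {
  ev <- randomEventTable(nSubj = 3)
  er <- computeErrorRate(ev)
  cells <- conditionCells(er, "rate")
  expect_equal(dim(cells), c(3L, 4L))
  expect_equal(cells["2", "AF-In"],
               er$rate[er$subject == 2 & er$feedback == "AF" &
                         er$position_class == "In"])
})
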
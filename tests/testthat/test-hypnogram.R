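test_that("minimum state-change rule merges sub-minimum runs", {
  ## interruption shorter than 1 min flanked by the same state is absorbed
  expect_equal(enforceMinStateRule(st("AS", 10, "QS", 1, "AS", 10)),
               rep("AS", 21))
  ## a full-length run is a scored state change
  x <- st("AS", 10, "QS", 2, "AS", 10)
  expect_equal(enforceMinStateRule(x), x)
  ## sub-minimum run between two different states continues the prior bout
  expect_equal(enforceMinStateRule(st("AS", 4, "QS", 1, "W", 4)),
               st("AS", 5, "W", 4))
  ## idempotence over random sequences
  set.seed(42)
  for (i in 1:25) {
    s <- sample(sleepStates(), 40, replace = TRUE)
    once <- enforceMinStateRule(s)
    expect_identical(enforceMinStateRule(once), once)
    expect_length(once, length(s))
  }
})

test_that("bout extraction traces match hand-worked cases", {
  ## recording ends during the active-sleep bout: right-censored
  b1 <- extractBouts(hyp(st("W", 4, "AS", 10)))
  expect_equal(nrow(bouts(b1)), 1)
  expect_equal(bouts(b1)$state, "AS")
  expect_equal(bouts(b1)$onset_min, 2)
  expect_equal(bouts(b1)$duration_min, 5)
  expect_equal(bouts(b1)$event_observed, 0L)
  expect_true(is.na(bouts(b1)$next_state))
  expect_equal(leftCensored(b1)$state, "W")   # first run excluded

  ## observed offset into quiet sleep, then a censored quiet-sleep bout
  b2 <- bouts(extractBouts(hyp(st("W", 4, "AS", 10, "QS", 6))))
  expect_equal(b2$duration_min, c(5, 3))
  expect_equal(b2$event_observed, c(1L, 0L))
  expect_equal(b2$next_state[1], "QS")

  ## a single uninterrupted run has no observed onset: empty modelling set
  b3 <- extractBouts(hyp(rep("AS", 20)))
  expect_equal(nrow(bouts(b3)), 0)
  expect_equal(nrow(leftCensored(b3)), 1)

  ## transitional sleep terminates the bout and is looked through
  b4 <- bouts(extractBouts(hyp(st("W", 4, "AS", 10, "TS", 2, "QS", 6))))
  expect_equal(b4$next_state[1], "QS")
  expect_equal(b4$duration_min[1], 5)   # TS time not part of the bout
  expect_equal(b4$event_observed[1], 1L)

  ## recording ending in full-length TS: offset observed, destination unknown
  b5 <- bouts(extractBouts(hyp(st("W", 4, "AS", 10, "TS", 2))))
  expect_equal(b5$event_observed, 1L)
  expect_true(is.na(b5$next_state))
})

test_that("bout durations partition the recording", {
  set.seed(7)
  cfg <- quietConfig()
  for (i in 1:10) {
    h <- simulateSubject(cfg, list(pma_weeks = runif(1, 28, 40)), seed = 100 + i)
    hc <- enforceMinStateRule(h)
    bs <- extractBouts(hc, applyMinRule = FALSE)
    tsMin <- sum(states(hc) == "TS") * epochLength(hc) / 60
    total <- sum(bouts(bs)$duration_min) + sum(leftCensored(bs)$duration_min) + tsMin
    expect_equal(total, recordingMinutes(h), tolerance = 1e-12)
    expect_true(all(bouts(bs)$duration_min >= 1))
  }
})

test_that("state percentages are epoch fractions summing to one", {
  p <- statePercentages(hyp(st("W", 5, "AS", 5)))
  expect_equal(unname(p[c("W", "AS")]), c(0.5, 0.5))
  expect_equal(unname(p[c("TS", "QS")]), c(0, 0))
  expect_equal(unname(statePercentages(hyp(rep("QS", 4)))[["QS"]]), 1)
  set.seed(3)
  for (i in 1:10) {
    p <- statePercentages(hyp(sample(sleepStates(), 33, replace = TRUE)))
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
  expect_error(Hypnogram("x", character(0)), "non-empty")
})

test_that("transition table counts offsets, unknowns and censorings", {
  b <- data.frame(
    subject_id = "a", state = "AS", onset_min = c(0, 10, 20),
    duration_min = c(5, 5, 5), onset_captured = 1L,
    event_observed = c(1L, 1L, 0L), next_state = c("QS", "W", NA),
    stringsAsFactors = FALSE)
  tab <- transitionTable(b)
  expect_equal(tab["AS", "QS"], 1L)
  expect_equal(tab["AS", "W"], 1L)
  expect_equal(tab["AS", "censored"], 1L)
  expect_equal(sum(tab["AS", ]), 3L)
  ## empty input: all-zero table
  empty <- new("BoutSet", bouts = neosleep:::emptyBoutFrame(),
               leftCensored = neosleep:::emptyBoutFrame())
  expect_true(all(transitionTable(empty) == 0L))
})

test_that("simulated cohorts reproduce the transition and occupancy structure", {
  cfg <- quietConfig()
  coh <- simulateCohort(cfg, 250, seed = 19)
  bs <- extractCohortBouts(coh$hypnograms)
  tab <- transitionTable(bs)
  ## marginals equal per-state bout counts
  expect_equal(unname(rowSums(tab)),
               unname(table(factor(bouts(bs)$state, levels = modelledStates()))[modelledStates()]),
               ignore_attr = TRUE)
  ## quiet sleep offsets almost always into active sleep (117/118 generating)
  qsObs <- tab["QS", "AS"] + tab["QS", "W"]
  expect_gt(qsObs, 20)
  expect_gte(tab["QS", "AS"] / qsObs, 0.95)
  ## censoring realism: active-sleep offsets unobserved far more often than QS
  b <- bouts(bs)
  censAS <- mean(b$event_observed[b$state == "AS"] == 0)
  censQS <- mean(b$event_observed[b$state == "QS"] == 0)
  expect_gt(censAS, censQS + 0.2)
  ## very-preterm occupancy pattern: wakefulness rare relative to active sleep
  vp <- simulateCohort(cfg, 40, seed = 23, covariateSampler = fixedCovSampler(pma = 29))
  occ <- rowMeans(vapply(vp$hypnograms, statePercentages, numeric(4)))
  expect_lt(occ[["W"]], occ[["AS"]] / 3)
})

test_that("cohort tables round-trip through write and read", {
  cfg <- quietConfig(lanceSchedule = list(prob_lance = 0.7, prob_non_noxious = 0.7))
  coh <- simulateCohort(cfg, 5, seed = 31)
  dir <- withr::local_tempdir()
  paths <- writeCohort(coh$hypnograms, dir)
  back <- readCohort(paths[["epochs"]], paths[["covariates"]], paths[["events"]])
  expect_setequal(names(back), vapply(coh$hypnograms, subjectId, character(1)))
  for (h in coh$hypnograms) {
    r <- back[[subjectId(h)]]
    expect_identical(states(r), states(h))
    expect_equal(covariates(r)$pma_weeks, covariates(h)$pma_weeks)
    expect_equal(covariates(r)$cortisol_ug_dl, covariates(h)$cortisol_ug_dl)
    expect_equal(events(r)$time_min, events(h)$time_min, tolerance = 1e-9)
    expect_equal(events(r)$kind, events(h)$kind)
  }
  ## single-subject reader demands an unambiguous file
  expect_error(readHypnogram(paths[["epochs"]]), "subjects")
  one <- readHypnogram(paths[["epochs"]], subject = subjectId(coh$hypnograms[[2]]))
  expect_identical(states(one), states(coh$hypnograms[[2]]))
})

test_that("malformed tables are rejected with informative errors", {
  dir <- withr::local_tempdir()
  ep <- file.path(dir, "bad.tsv")
  writeLines(c("#epoch_length_s=30", "subject_id\tepoch_index\tstate",
               "a\t0\tW", "a\t1\tX"), ep)
  expect_error(readCohort(ep), "unknown state code 'X'")
  cv <- file.path(dir, "cov.csv")
  writeLines(c("subject_id,pma_weeks", "a,33"), cv)
  ok <- file.path(dir, "ok.tsv")
  writeLines(c("#epoch_length_s=30", "subject_id\tepoch_index\tstate",
               "a\t0\tW", "a\t1\tAS", "a\t2\tAS"), ok)
  expect_error(readCohort(ok, covariatePath = cv), "missing column")
  ## 3-row table parses to a 90-second hypnogram
  h <- readHypnogram(ok)
  expect_equal(length(states(h)), 3)
  expect_equal(recordingMinutes(h), 1.5)
})
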
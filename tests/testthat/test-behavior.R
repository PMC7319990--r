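test_that("trial scoring implements the task rules", {
  win <- c(1.7, 3.7)
  ## rewarded texture + licks + 2-fold rate increase -> hit
  expect_equal(scoreTrial("P120", "P120", c(2.0, 2.5, 3.0), win,
                          baseline_lick_rate = 1, texture_lick_rate = 3),
               "hit")
  ## rate rule not met -> miss despite licking
  expect_equal(scoreTrial("P120", "P120", c(2.0), win,
                          baseline_lick_rate = 2, texture_lick_rate = 3),
               "miss")
  expect_equal(scoreTrial("P120", "P120", numeric(0), win), "miss")
  expect_equal(scoreTrial("P280", "P120", c(2.0), win), "FA")
  expect_equal(scoreTrial("P280", "P120", c(0.5), win), "CR")
  ## contingency epoch decides which stimulus is Go
  expect_equal(scoreTrial("P280", "P280", c(2.0), win,
                          baseline_lick_rate = 0, texture_lick_rate = 1),
               "hit")
})

test_that("hit/FA rates and performance are exact ratios", {
  r <- behaviorRates(c(rep("hit", 30), rep("miss", 10)))
  expect_equal(r$hit_rate, 0.75)
  expect_true(is.na(r$fa_rate))
  r2 <- behaviorRates(c(rep("hit", 2), rep("miss", 2), rep("FA", 2),
                        rep("CR", 2)))
  expect_equal(r2$hit_rate, 0.5)
  expect_equal(r2$fa_rate, 0.5)
  expect_equal(r2$performance, 50)
  expect_equal(behaviorRates(c("hit", "CR"))$performance, 100)
})

test_that("performance decomposes into the rate identity", {
  tr <- trials(fixtureSession())
  r <- behaviorRates(tr$outcome)
  nGo <- sum(tr$outcome %in% c("hit", "miss"))
  nNo <- sum(tr$outcome %in% c("FA", "CR"))
  expect_equal(r$performance,
               100 * (r$hit_rate * nGo + (1 - r$fa_rate) * nNo) /
                 (nGo + nNo))
})

test_that("rolling curves are center-labelled and handle degenerate input", {
  tr <- data.frame(outcome = rep(c("hit", "CR"), 100))
  c1 <- rollingCurve(tr, window = 50)
  expect_true(all(c1$performance[!is.na(c1$performance)] == 100))
  expect_true(is.na(c1$performance[1]))
  tr2 <- data.frame(outcome = rep("FA", 80))
  c2 <- rollingCurve(tr2, window = 40)
  expect_true(all(c2$performance[!is.na(c2$performance)] == 0))
  expect_warning(rollingCurve(data.frame(outcome = "hit"), 200), "fewer")
})

test_that("the expert criterion needs two consecutive sessions at 70%", {
  expect_equal(detectExpertCriterion(c(60, 72, 71, 80)), 3L)
  expect_equal(detectExpertCriterion(rep(65, 6)), NA_integer_)
  expect_equal(detectExpertCriterion(c(75, 74)), 2L)
  expect_equal(detectExpertCriterion(c(75, 60, 75, 80)), 4L)
})

test_that("realignment is a pure index shift", {
  expect_equal(realignToCriterion(1:10, 0), 1:10)
  expect_equal(realignToCriterion(500, 640), -140)
  tr <- trials(fixtureSession())
  t1 <- realignToCriterion(tr$trial_id, 300)
  expect_equal(table(tr$outcome),
               table(tr$outcome[order(t1)]))
  expect_error(realignToCriterion(1:5, NA_integer_), "undefined")
})

test_that("criterion trial anchors at the first window reaching threshold", {
  tr <- trials(fixtureSession())
  perf <- sessionPerformance(tr)
  cs <- detectExpertCriterion(perf$performance)
  ct <- criterionTrial(tr, cs)
  expect_false(is.na(ct))
  curve <- rollingCurve(tr, 200)
  expect_gte(curve$performance[curve$trial == ct], 70)
  before <- curve$performance[curve$trial < ct &
                                curve$trial >= (cs - 2) * 150 + 1]
  expect_true(all(before < 70 | is.na(before)))
})

test_that("learning onset detection finds a programmed divergence", {
  ## three subjects whose hit and FA rates separate at a known trial
  mk <- function(seed) {
    set.seed(seed)
    n <- 600; tstar <- 300
    go <- rep(c(TRUE, FALSE), n / 2)
    pLick <- ifelse(seq_len(n) < tstar, 0.5, ifelse(go, 0.95, 0.05))
    lick <- runif(n) < pLick
    out <- ifelse(go, ifelse(lick, "hit", "miss"),
                  ifelse(lick, "FA", "CR"))
    d <- rollingCurve(data.frame(outcome = out), window = 100)
    d$t <- seq_len(n) - 500  # criterion placed at trial 500
    d
  }
  curves <- lapply(1:4, mk)
  res <- detectLearningOnset(curves, n_boot = 200, seed = 1)
  expect_false(is.na(res$onset))
  ## divergence programmed at realigned -200: detection can lead by at most
  ## one window (partial overlap) and must not lag past the ramp
  expect_gt(res$onset, -200 - 100)
  expect_lt(res$onset, -90)
  ## identical hit and FA rate curves never separate
  flat <- lapply(5:7, function(s) {
    out <- rep(c("hit", "FA"), 200)
    d <- rollingCurve(data.frame(outcome = out), window = 100)
    d$t <- seq_len(400) - 400
    d
  })
  expect_true(is.na(detectLearningOnset(flat, n_boot = 200, seed = 2)$onset))
  expect_error(detectLearningOnset(curves[1]))
})

test_that("median splits assign ties to the low set", {
  s <- splitByBehaviorRate(c(1, 2, 3, 4))
  expect_equal(s$low, 1:2)
  expect_equal(s$high, 3:4)
  sAll <- splitByBehaviorRate(rep(2, 5))
  expect_equal(sAll$low, 1:5)
  expect_length(sAll$high, 0)
  set.seed(1)
  sc <- splitByBehaviorRate(runif(101))
  expect_lte(abs(length(sc$low) - length(sc$high)), 1)
  expect_error(splitByBehaviorRate(1), "two trials")
})

test_that("event-rate traces count events in a centered 100-ms window", {
  at <- seq(0.05, 0.95, by = 0.1)
  expect_equal(eventRateTrace(numeric(0), at), rep(0, length(at)))
  ev <- seq(0.005, 0.995, length.out = 10)
  expect_equal(mean(eventRateTrace(ev, at)), 10, tolerance = 0.2)
  one <- eventRateTrace(0.5, seq(0, 1, by = 0.01))
  expect_equal(max(one), 1 / 0.1)
  expect_equal(sum(one > 0) * 0.01, 0.1, tolerance = 0.02)
})

test_that("learning phases partition the experiment around the reversal", {
  ph <- fixturePhases()
  expect_equal(ph$phase, c("pre_expert", "post_naive", "post_expert"))
  expect_true(all(ph$from <= ph$to))
  expect_equal(ph$to[2] + 1L, ph$from[3])
  expect_equal(ph$from[2], 301)
  expect_equal(attr(ph, "criterion_trial"), ph$from[3])
  expect_error(phaseTrials(ph, "bogus"), "unknown")
})
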
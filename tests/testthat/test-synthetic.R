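test_that("stimulus sequences respect the run-length constraint and marginal", {
  for (seed in 1:20) {
    s <- generateStimulusSequence(2000, seed = seed)
    expect_true(all(s %in% c("P120", "P280")))
    expect_lte(max(rle(s)$lengths), 4)
  }
  s <- generateStimulusSequence(5000, seed = 99)
  se <- sqrt(0.25 / 5000)
  expect_lt(abs(mean(s == "P120") - 0.5), 3 * se)
  expect_length(generateStimulusSequence(1, seed = 1), 1)
  alt <- generateStimulusSequence(50, max_consecutive = 1, seed = 5)
  expect_true(all(rle(alt)$lengths == 1))
})

test_that("a biased marginal survives the run-length constraint approximately", {
  ## forcing the alternative label after a maximal run pulls an asymmetric
  ## marginal toward 0.5; the draw probability is still renormalised, so
  ## the shift stays small
  s <- generateStimulusSequence(20000, p_go = 0.4, max_consecutive = 4,
                                seed = 11)
  expect_gt(mean(s == "P120"), 0.39)
  expect_lt(mean(s == "P120"), 0.45)
  expect_lte(max(rle(s)$lengths), 4)
})

test_that("agent outcomes are consistent with stimulus, contingency and licks", {
  tr <- trials(fixtureSession())
  go <- tr$stimulus == tr$rewarded_stimulus
  expect_true(all(tr$outcome[go] %in% c("hit", "miss")))
  expect_true(all(tr$outcome[!go] %in% c("FA", "CR")))
  ## conservation: hit+miss = Go count, FA+CR = No-go count
  expect_equal(sum(tr$outcome %in% c("hit", "miss")), sum(go))
  expect_equal(sum(tr$outcome %in% c("FA", "CR")), sum(!go))
  ## FA and hit trials carry a texture-window lick; CR never does
  expect_true(all(tr$n_licks_texture[tr$outcome %in% c("hit", "FA")] > 0))
  expect_true(all(tr$n_licks_texture[tr$outcome == "CR"] == 0))
  ## reaction time present iff a texture-window lick occurred
  expect_equal(is.na(tr$reaction_time_s), tr$n_licks_texture == 0)
})

test_that("a perfect agent makes only correct choices", {
  stim <- generateStimulusSequence(200, seed = 2)
  ag <- agentParams(p_correct_start = 1, p_correct_expert = 1)
  tr <- simulateAgent(stim, rep("P120", 200), ag, simConfig(), seed = 4)
  ## every No-go trial is withheld; every Go trial is licked. A Go trial
  ## may still be scored a miss by the 2-fold lick-rate reward rule, so
  ## misses are rare and always carry texture licks (no policy errors)
  expect_true(all(tr$outcome[tr$stimulus != "P120"] == "CR"))
  expect_true(all(tr$n_licks_texture[tr$stimulus == "P120"] > 0))
  expect_gt(mean(tr$outcome %in% c("hit", "CR")), 0.97)
})

test_that("a chance-level agent stays near 50% rolling performance", {
  n <- 4000
  stim <- generateStimulusSequence(n, seed = 3)
  ag <- agentParams(p_correct_start = 0.5, p_correct_expert = 0.500001,
                    learning_midpoint = 1e9)
  tr <- simulateAgent(stim, rep("P120", n), ag, simConfig(), seed = 5)
  curve <- rollingCurve(tr, 200)
  perf <- curve$performance[!is.na(curve$performance)] / 100
  ## binomial oracle for the rolling mean's sampling distribution
  se <- sqrt(0.25 / 200)
  expect_lt(abs(mean(perf) - 0.5), 0.015)
  expect_lt(mean(abs(perf - 0.5) > 3 * se), 0.10)
})

test_that("agent reaction times recover the programmed latency distribution", {
  tr <- trials(fixtureSession())
  rt <- tr$reaction_time_s[tr$outcome == "hit"]
  ag <- fixtureAgent()
  ## programmed: 0.1 s dead time + gamma(shape, rate), truncated at 1.9 s
  progMean <- 0.1 + ag$lick_latency_shape / ag$lick_latency_rate
  expect_gt(length(rt), 100)
  expect_lt(abs(mean(rt) - progMean), 0.1)
})

test_that("length mismatch between stimuli and contingency is rejected", {
  expect_error(simulateAgent(c("P120", "P280"), "P120"), "equal length")
})

test_that("zero-amplitude neurons give exchangeable texture responses", {
  sess <- fixtureSession()
  gt <- groundTruth(sess)
  resp <- fixtureResponses()
  j <- which(gt$true_class == "nonselective")[1]
  tr <- trials(sess)
  a <- resp[j, tr$stimulus == "P120"]
  b <- resp[j, tr$stimulus == "P280"]
  expect_gt(stats::t.test(a, b)$p.value, 0.01)
})

test_that("the control channel is independent of behaviour", {
  sess <- fixtureSession()
  ctrlResp <- trialResponses(fixturePrep()$dff_control$dff, sess)
  tr <- trials(sess)
  p <- vapply(seq_len(nrow(ctrlResp)), function(j) {
    stats::t.test(ctrlResp[j, tr$stimulus == "P120"],
                  ctrlResp[j, tr$stimulus == "P280"])$p.value
  }, numeric(1))
  expect_gt(mean(p > 0.05), 0.8)
})

test_that("value neurons track the believed contingency across reversal", {
  sess <- fixtureSession()
  gt <- groundTruth(sess)
  resp <- fixtureResponses()
  tr <- trials(sess)
  j <- which(gt$true_class == "value")[1]
  pre <- tr$trial_id >= 150 & tr$trial_id <= 300
  post <- tr$trial_id >= 600
  diPre <- selectivityIndex(resp[j, pre & tr$stimulus == "P120"],
                            resp[j, pre & tr$stimulus == "P280"])
  diPost <- selectivityIndex(resp[j, post & tr$stimulus == "P120"],
                             resp[j, post & tr$stimulus == "P280"])
  expect_gt(as.numeric(diPre), 0.3)
  expect_lt(as.numeric(diPost), -0.3)
})

test_that("identical seed and config reproduce the session bit-identically", {
  cfg <- simConfig(n_sessions_pre = 1, n_sessions_post = 1,
                   trials_per_session = 30)
  co <- neuronCohort(n_per_class = c(texture_P120 = 1, nonselective = 1),
                     seed = 2)
  ag <- fixtureAgent(reversal_trial = 31, relearning_midpoint = 45)
  s1 <- simulateExperiment(cfg, ag, co, seed = 42)
  s2 <- simulateExperiment(cfg, ag, co, seed = 42)
  expect_identical(activity(s1), activity(s2))
  expect_identical(controlChannel(s1), controlChannel(s2))
  expect_identical(trials(s1)$outcome, trials(s2)$outcome)
  s3 <- simulateExperiment(cfg, ag, co, seed = 43)
  expect_false(identical(activity(s1), activity(s3)))
})

test_that("invalid simulation parameters are rejected", {
  expect_error(simConfig(p_go = 0))
  expect_error(simConfig(texture_s = -1))
  expect_error(agentParams(p_correct_start = 0.4))
  expect_error(neuronCohort(n_per_class = c(bogus = 3)))
})
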
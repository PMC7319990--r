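test_that("hit trials are partitioned by their immediate predecessor", {
  p <- partitionHits(c("FA", "hit"))
  expect_equal(p$hit_post_FA, 2L)
  p2 <- partitionHits(c("hit", "hit"))
  expect_equal(p2$hit_post_hit, 2L)
  expect_equal(p2$hit_other, 1L)
  p3 <- partitionHits(c("CR", "hit"))
  expect_equal(p3$hit_other, 2L)
  expect_length(p3$hit_post_FA, 0)
  ## partition covers all hits exactly once
  out <- trials(fixtureSession())$outcome
  p4 <- partitionHits(out)
  allIdx <- sort(c(p4$hit_post_FA, p4$hit_post_hit, p4$hit_other))
  expect_equal(allIdx, which(out == "hit"))
})

test_that("the error-history formula is computed per window", {
  ## craft a sequence whose window means are known exactly
  outcomes <- rep(c("FA", "hit", "hit", "CR", "hit"), 5)
  resp <- numeric(25)
  p <- partitionHits(outcomes)
  resp[p$hit_post_FA] <- 1.2
  resp[p$hit_post_hit] <- 0.8
  resp[p$hit_other] <- 1.0
  eh <- errorHistoryCurve(resp, outcomes, seq_len(25) - 13, window = 25)
  nFA <- length(p$hit_post_FA); nHH <- length(p$hit_post_hit)
  nOther <- length(p$hit_other)
  denom <- (1.2 * nFA + 0.8 * nHH + 1.0 * nOther) / (nFA + nHH + nOther)
  expect_equal(eh$eh, (1.2 - 0.8) / denom)
  expect_equal(eh$t, 0)
  ## equal conditioned means give zero
  resp0 <- resp; resp0[] <- 0.9
  eh0 <- errorHistoryCurve(resp0, outcomes, seq_len(25) - 13, window = 25)
  expect_equal(eh0$eh, 0)
  ## uniform scaling leaves the ratio unchanged
  eh2 <- errorHistoryCurve(2 * resp, outcomes, seq_len(25) - 13,
                           window = 25)
  expect_equal(eh2$eh, eh$eh)
})

test_that("error history is antisymmetric in the two conditioned sets", {
  ## periodic outcomes give equally sized conditioned sets in a full window
  set.seed(41)
  outcomes <- rep(c("FA", "hit", "hit", "CR", "hit"), 5)
  resp <- rnorm(25, 1, 0.2)
  p <- partitionHits(outcomes)
  expect_equal(length(p$hit_post_FA), length(p$hit_post_hit))
  eh <- errorHistoryCurve(resp, outcomes, seq_len(25) - 13, window = 25)
  ## exchange the responses of the two conditioned sets wholesale
  respSwap <- resp
  respSwap[p$hit_post_FA] <- resp[p$hit_post_hit]
  respSwap[p$hit_post_hit] <- resp[p$hit_post_FA]
  ehS <- errorHistoryCurve(respSwap, outcomes, seq_len(25) - 13,
                           window = 25)
  expect_equal(ehS$eh, -eh$eh, tolerance = 1e-12)
})

test_that("windows without a conditioned hit yield missing values", {
  outcomes <- c("CR", "hit", rep("CR", 30))
  resp <- rnorm(32)
  eh <- errorHistoryCurve(resp, outcomes, seq_len(32), window = 21)
  expect_true(all(is.na(eh$eh)))
})

test_that("permutation bounds are reproducible and detect a programmed boost", {
  set.seed(43)
  n <- 400
  outcomes <- sample(c("hit", "FA"), n, replace = TRUE, prob = c(0.6, 0.4))
  resp <- rnorm(n, 1, 0.1)
  p <- partitionHits(outcomes)
  resp[p$hit_post_FA] <- resp[p$hit_post_FA] * 1.6
  tA <- seq_len(n) - 200
  e1 <- errorHistoryNull(resp, outcomes, tA, window = 101, step = 10,
                         n_perm = 300, seed = 6)
  e2 <- errorHistoryNull(resp, outcomes, tA, window = 101, step = 10,
                         n_perm = 300, seed = 6)
  expect_identical(e1, e2)
  expect_gt(mean(e1$significant, na.rm = TRUE), 0.9)
  expect_true(all(e1$eh > e1$ci_high, na.rm = TRUE))
})

test_that("exchangeable responses are flagged at about the nominal rate", {
  set.seed(45)
  hits <- 0; total <- 0
  for (i in 1:120) {
    outcomes <- sample(c("hit", "FA"), 120, replace = TRUE)
    resp <- rnorm(120)
    e <- errorHistoryNull(resp, outcomes, seq_len(120), window = 101,
                          step = 20, n_perm = 300, seed = i)
    hits <- hits + sum(e$significant, na.rm = TRUE)
    total <- total + sum(!is.na(e$eh) & !is.na(e$ci_low))
  }
  expect_gt(hits / total, 0.015)
  expect_lt(hits / total, 0.10)
})

test_that("significant fractions aggregate per class", {
  mkSeries <- function(sig) {
    data.frame(t = -5:5, eh = 0.1, significant = sig)
  }
  series <- list(a = mkSeries(FALSE), b = mkSeries(FALSE),
                 c = mkSeries(TRUE))
  cls <- data.frame(neuron_id = c("a", "b", "c"),
                    learning_class = c("gained", "gained", "reversed"))
  f <- significantFractionByClass(series, cls)
  expect_equal(f$fraction_significant[f$class == "gained"], 0)
  expect_equal(f$fraction_significant[f$class == "reversed"], 1)
})

test_that("response divergence is detected for a programmed boost only", {
  mkSub <- function(seed, boost) {
    set.seed(seed)
    n <- 700
    outcomes <- sample(c("hit", "FA"), n, replace = TRUE,
                       prob = c(0.6, 0.4))
    resp <- rnorm(n, 1, 0.15)
    if (boost) {
      p <- partitionHits(outcomes)
      late <- p$hit_post_FA[p$hit_post_FA > 300]
      resp[late] <- resp[late] * 1.7
    }
    list(responses = resp, outcomes = outcomes, t_axis = seq_len(n) - 650)
  }
  boosted <- lapply(1:3, mkSub, boost = TRUE)
  dv <- responseDivergenceTrial(boosted, window = 101, step = 5,
                                n_boot = 200, seed = 3)
  expect_false(is.na(dv$divergence))
  ## boost begins at realigned -349: detection may lead by up to half a
  ## window (partial overlap) and must not lag past one full window
  expect_gt(dv$divergence, -349 - 51)
  expect_lt(dv$divergence, -349 + 101)
  expect_error(responseDivergenceTrial(boosted[1]))
  flat <- lapply(4:6, mkSub, boost = FALSE)
  dvF <- responseDivergenceTrial(flat, window = 101, step = 5,
                                 n_boot = 200, seed = 3)
  if (!is.na(dvF$divergence)) expect_gt(dvF$divergence, -120)
})

test_that("spontaneous co-fluctuations rise for neurons sharing a latent drive", {
  co <- neuronCohort(n_per_class = c(texture_P120 = 4, nonselective = 4),
                     seed = 5)
  pre <- simulateSpontaneous(co, duration_s = 120, seed = 11)
  post <- simulateSpontaneous(co, duration_s = 120,
                              shared_classes = "texture_P120",
                              shared_amp = 3, seed = 12)
  cPre <- cofluctuation(pre$dff)
  cPost <- cofluctuation(post$dff)
  gg <- comparePhases(cPre, cPost, co$neuron_id[co$true_class ==
                                                  "texture_P120"])
  others <- comparePhases(cPre, cPost, co$neuron_id[co$true_class ==
                                                      "nonselective"])
  expect_gt(mean(gg$delta), 0.1)
  expect_lt(abs(mean(others$delta)), 0.1)
  ## identical traces correlate perfectly; independent noise near zero
  x <- matrix(rnorm(2000), 2, byrow = TRUE)
  x[2, ] <- x[1, ]
  expect_equal(cofluctuation(x)$correlation, 1)
  y <- matrix(rnorm(40000), 4)
  expect_lt(max(abs(cofluctuation(y)$correlation)), 0.05)
})
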
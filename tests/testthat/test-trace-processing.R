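test_that("neuropil correction applies F - r * Fneuropil", {
  expect_equal(neuropilCorrect(100, 50, 0.7), 65)
  m <- matrix(rnorm(20), 4)
  expect_equal(neuropilCorrect(m, m * 0 + 1, 0), m)
  expect_equal(neuropilCorrect(m, m, 1), m * 0)
  expect_error(neuropilCorrect(m, m[, 1:3]), "shape")
  expect_error(neuropilCorrect(m, m, r = 1.5))
})

test_that("per-trial detrending subtracts each trial's 8th percentile", {
  expect_equal(detrendTrial(rep(3.5, 20)), rep(0, 20))
  x <- as.numeric(0:99)
  expect_equal(detrendTrial(x), x - quantile(x, 0.08, type = 7,
                                             names = FALSE))
  expect_lt(min(detrendTrial(x)), 0)
  ## two concatenated trials, each detrended by its own percentile
  y <- c(x, x + 50)
  ft <- rep(1:2, each = 100)
  d <- detrendTrial(y, ft)
  expect_equal(d[1:100], d[101:200])
  expect_error(detrendTrial(numeric(0)), "empty")
})

test_that("dF/F0 follows the trial-baseline-median dialect", {
  nf <- 20
  phase <- rep(c(rep("baseline", 10), rep("texture", 10)), 3)
  ft <- rep(1:3, each = nf)
  f <- rep(c(rep(10, 10), rep(15, 10)), 3)
  nt <- computeDFF(matrix(f, 1), ft, phase)
  expect_equal(unique(nt$dff[phase == "texture"]), 0.5)
  expect_equal(unique(nt$dff[phase == "baseline"]), 0)
  ## constant trace at its own baseline
  nt0 <- computeDFF(matrix(rep(10, 60), 1), ft, phase)
  expect_true(all(nt0$dff == 0))
})

test_that("the 30th-percentile dialect matches an order-statistic oracle", {
  set.seed(8)
  x <- rnorm(120, mean = 50, sd = 5)
  ft <- rep(1:3, each = 40)
  nt <- computeDFF(matrix(x, 1), ft, f0_mode = "percentile_30")
  for (k in 1:3) {
    seg <- x[ft == k]
    s <- sort(seg)
    ## type-7 linear interpolation between order statistics
    h <- (length(seg) - 1) * 0.3 + 1
    oracle <- s[floor(h)] + (h - floor(h)) * (s[ceiling(h)] - s[floor(h)])
    expect_equal(nt$f0[1, k], oracle)
    expect_equal(nt$dff[ft == k], (seg - oracle) / oracle)
  }
})

test_that("non-positive F0 masks the neuron-trial instead of dividing", {
  x <- c(rnorm(40, 50, 1), rnorm(40, -50, 1))
  ft <- rep(1:2, each = 40)
  nt <- computeDFF(matrix(x, 1), ft, f0_mode = "percentile_30")
  expect_true(all(is.finite(nt$dff[ft == 1])))
  expect_true(all(is.na(nt$dff[ft == 2])))
  expect_equal(nt$valid[1, ], c(TRUE, FALSE))
})

test_that("dF/F0 is invariant to a common positive gain on both raw channels", {
  sess <- fixtureSession()
  sub <- 1:500
  fm <- activity(sess)[1:2, sub]
  fn <- neuropilChannel(sess)[1:2, sub]
  ft <- frameTrial(sess)[sub]
  ph <- framePhase(sess)[sub]
  pipe <- function(g) {
    f <- detrendTrial(neuropilCorrect(g * fm, g * fn, 0.7), ft)
    computeDFF(f, ft, ph)$dff
  }
  expect_equal(pipe(1), pipe(3.7))
})

test_that("Savitzky-Golay smoothing reproduces low-order polynomials", {
  t <- seq(0, 5, by = 1 / 11.5)
  quad <- 2 + 0.5 * t - 0.3 * t^2
  expect_lt(max(abs(smoothDisplay(quad, 11.5) - quad)), 1e-9)
  expect_equal(smoothDisplay(rep(4, 60), 11.5), rep(4, 60))
  expect_error(smoothDisplay(rnorm(60), 11.5, order = 2, span_s = 0.2),
               "span")
})

test_that("Savitzky-Golay smoothing attenuates white noise per the filter gain", {
  set.seed(4)
  x <- rnorm(20000)
  sm <- smoothDisplay(x, 11.5)
  n <- 7  # 500 ms at 11.5 Hz, rounded to odd
  gain <- sum(signal::sgolay(p = 2, n = n)[(n + 1) / 2, ]^2)
  ratio <- var(sm[n:(length(sm) - n)]) / var(x)
  expect_lt(ratio, 1)
  expect_lt(abs(ratio - gain) / gain, 0.15)
})

test_that("deconvolution recovers ideal AR(1) transients", {
  g <- exp(-1 / (1.5 * 11.5))
  ## single ideal transient: instant rise at frame 50, exponential decay
  y <- numeric(200)
  y[50:200] <- g^(0:150)
  inf <- inferSpikeRates(y, deconvParams(ar_decay = g))
  r <- inf$rates
  expect_true(all(r >= 0))
  expect_gt(sum(r[49:51]) / sum(r), 0.9)
  ## two well-separated transients with amplitudes a and 2a
  y2 <- numeric(400)
  y2[50:200] <- g^(0:150)
  y2[250:400] <- y2[250:400] + 2 * g^(0:150)
  r2 <- inferSpikeRates(y2, deconvParams(ar_decay = g))$rates
  m1 <- sum(r2[45:150]); m2 <- sum(r2[245:350])
  expect_lt(abs(m2 / m1 - 2), 0.1)
  expect_equal(inferSpikeRates(rep(0, 100),
                               deconvParams(ar_decay = g))$rates,
               rep(0, 100))
  expect_error(inferSpikeRates(c(1, NA, 3)), "non-finite")
})

test_that("deconvolution round trip beats the injected noise variance", {
  set.seed(6)
  g <- 0.94
  n <- 2000
  spikes <- rpois(n, 0.05)
  clean <- as.numeric(stats::filter(spikes, g, method = "recursive"))
  noise_sd <- 0.3
  y <- clean + rnorm(n, 0, noise_sd)
  inf <- inferSpikeRates(y, deconvParams(ar_decay = g))
  ## reconvolving the rates reproduces the denoised trace
  reconv <- as.numeric(stats::filter(inf$rates, g, method = "recursive"))
  expect_equal(reconv, inf$denoised, tolerance = 1e-8)
  resid <- (y - as.numeric(inf$background)) - inf$denoised
  expect_lt(var(resid), noise_sd^2)
})

test_that("half-maximum onsets handle steps, ramps and flat traces", {
  t <- seq(-1, 2, by = 0.01)
  step <- as.numeric(t >= 0.3)
  expect_equal(halfMaxOnset(step, t), 0.3, tolerance = 0.011)
  ramp <- pmin(pmax(t, 0), 1)
  expect_equal(halfMaxOnset(ramp, t), 0.5, tolerance = 0.011)
  expect_true(is.na(halfMaxOnset(rep(0, length(t)), t)))
})

test_that("stimulus-locked activity starts before the first lick", {
  sess <- fixtureSession()
  gt <- groundTruth(sess)
  tr <- trials(sess)
  dff <- fixturePrep()$dff$dff
  hits <- tr$outcome == "hit" & tr$trial_id >= 150 & tr$trial_id <= 300
  expert_hits <- tr$trial_id[hits]
  tex <- responseOnset(dff, sess, expert_hits, "texture_onset")
  lick <- responseOnset(dff, sess, expert_hits, "first_lick")
  sel <- gt$true_class == "texture_P120"
  ok <- sel & !is.na(tex) & !is.na(lick)
  expect_gt(sum(ok), 0)
  expect_true(all(tex[ok] > 0 & tex[ok] < 2))
  ## texture-locked activity: relative to the (later) lick the onset shifts
  ## earlier by about the reaction time, so in absolute trial time both
  ## alignments agree and the response starts before it would if lick-locked
  meanRT <- mean(tr$reaction_time_s[hits], na.rm = TRUE)
  expect_lt(mean(lick[ok]), mean(tex[ok]))
  expect_lt(abs(mean(lick[ok]) - (mean(tex[ok]) - meanRT)), 0.3)
})

test_that("preprocessing emits a QC table and masks nothing on clean data", {
  prep <- fixturePrep()
  expect_equal(nrow(prep$qc), nrow(fixtureSession()))
  expect_true(all(prep$qc$n_masked_trials == 0))
  expect_true(all(prep$qc$f0_median > 0))
})
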
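#' Simulation configuration
#'
#' Bundles the session-level constants of the synthetic Go/No-go reversal
#' experiment. Defaults reproduce the task timing of the texture
#' discrimination paradigm: a 1-s pre-stimulus baseline, a 200-ms auditory
#' cue, a 500-ms delay and a 2-s texture presentation, imaged at 11.5 Hz,
#' with both textures presented at 50% probability and never more than four
#' consecutive identical presentations.
#'
#' @param n_sessions_pre,n_sessions_post sessions before / after the
#'   contingency reversal.
#' @param trials_per_session trials per session.
#' @param frame_rate imaging rate, Hz.
#' @param baseline_s,cue_s,delay_s,texture_s,post_s trial phase durations, s.
#' @param p_go probability of the initially rewarded texture (P120) per trial.
#' @param max_consecutive longest permitted run of identical stimuli.
#' @param spike_amp fluorescence transient amplitude per inferred event,
#'   dF/F0 units.
#' @param belief_alpha per-trial learning rate of the contingency belief that
#'   drives value-class responses.
#' @param eh_boost fractional response boost of value-class neurons on hit
#'   trials that follow a false alarm, active during relearning.
#' @param poisson_spikes draw spikes as an inhomogeneous Poisson process
#'   (`TRUE`, default); `FALSE` uses the expected rate directly, giving
#'   noiseless deterministic responses.
#' @param f0_level,npil_amp mean somatic fluorescence and neuropil
#'   fluctuation amplitude, arbitrary fluorescence units.
#' @return Named list of class `simConfig`.
#' @export
simConfig <- function(n_sessions_pre = 4, n_sessions_post = 4,
                      trials_per_session = 250, frame_rate = 11.5,
                      baseline_s = 1.0, cue_s = 0.2, delay_s = 0.5,
                      texture_s = 2.0, post_s = 2.0,
                      p_go = 0.5, max_consecutive = 4,
                      spike_amp = 0.2, belief_alpha = 0.002,
                      eh_boost = 0.5, poisson_spikes = TRUE,
                      f0_level = 100, npil_amp = 10) {
  layout <- c(baseline_s = baseline_s, cue_s = cue_s, delay_s = delay_s,
              texture_s = texture_s, post_s = post_s)
  stopifnot(all(layout > 0), p_go > 0, p_go < 1, max_consecutive >= 1,
            frame_rate > 0)
  structure(list(
    n_sessions_pre = n_sessions_pre, n_sessions_post = n_sessions_post,
    trials_per_session = trials_per_session, frame_rate = frame_rate,
    layout = as.list(layout), p_go = p_go, max_consecutive = max_consecutive,
    spike_amp = spike_amp, belief_alpha = belief_alpha, eh_boost = eh_boost,
    poisson_spikes = poisson_spikes, f0_level = f0_level,
    npil_amp = npil_amp
  ), class = "simConfig")
}

#' Learning-agent parameters
#'
#' The agent's probability of a correct choice follows a logistic ramp in
#' trial index from `p_correct_start` (chance) towards `p_correct_expert`,
#' collapses back to chance at the contingency reversal, and recovers along a
#' second logistic centred on `relearning_midpoint`.
#'
#' @param p_correct_start,p_correct_expert asymptotes of the learning curve;
#'   must satisfy `0.5 <= start < expert <= 1`.
#' @param learning_midpoint,learning_slope midpoint (trial) and slope
#'   (1/trials) of the pre-reversal logistic.
#' @param reversal_trial first trial of the reversed contingency (`NA`: set
#'   by [simulateExperiment()]).
#' @param relearning_midpoint midpoint of the post-reversal logistic, in
#'   trials from experiment start (`NA`: `reversal_trial + 450`).
#' @param lick_rate_go lick rate on lick trials during the texture window,
#'   events/s.
#' @param lick_rate_nogo residual lick rate outside the texture window,
#'   events/s.
#' @param whisk_rate_mean,whisk_rate_sd across-trial distribution of the
#'   per-trial whisking rate, events/s.
#' @param lick_latency_shape,lick_latency_rate gamma parameters of the first
#'   lick latency after texture onset (plus a 100-ms dead time), giving a
#'   reaction-time distribution centred near 0.5 s.
#' @return Named list of class `agentParams`.
#' @export
agentParams <- function(p_correct_start = 0.5, p_correct_expert = 0.82,
                        learning_midpoint = 300, learning_slope = 0.02,
                        reversal_trial = NA_integer_,
                        relearning_midpoint = NA_real_,
                        lick_rate_go = 4, lick_rate_nogo = 0.2,
                        whisk_rate_mean = 6, whisk_rate_sd = 2,
                        lick_latency_shape = 4, lick_latency_rate = 10) {
  stopifnot(p_correct_start >= 0.5, p_correct_start < p_correct_expert ||
              p_correct_start == p_correct_expert,
            p_correct_expert <= 1)
  structure(as.list(environment()), class = "agentParams")
}

#' Per-neuron simulation specification
#'
#' @param n_per_class named integer vector: neurons per ground-truth class.
#'   Valid classes: `texture_P120`, `texture_P280`, `choice`, `value`,
#'   `whisk_coupled`, `lick_coupled`, `sound`, `touch_nonselective`,
#'   `nonselective`.
#' @param response_amp evoked event rate during the driving condition,
#'   events/s.
#' @param noise_sd per-frame measurement noise, dF/F0 units.
#' @param kernel_rise_s,kernel_decay_s calcium-indicator kernel time
#'   constants, s (GCaMP6s-like defaults).
#' @param neuropil_gain contamination coefficient of the shared neuropil
#'   signal in the measured trace.
#' @param amp_jitter multiplicative uniform jitter (+/- fraction) applied to
#'   `response_amp` per neuron.
#' @param seed RNG seed for the jitter.
#' @return data.frame, one row per neuron, with the NeuronSpec fields.
#' @export
neuronCohort <- function(n_per_class = c(texture_P120 = 4, texture_P280 = 2,
                                         choice = 3, value = 3,
                                         whisk_coupled = 3, lick_coupled = 3,
                                         sound = 2, touch_nonselective = 3,
                                         nonselective = 7),
                         response_amp = 5, noise_sd = 0.1,
                         kernel_rise_s = 0.2, kernel_decay_s = 1.5,
                         neuropil_gain = 0.7, amp_jitter = 0.2,
                         seed = NULL) {
  valid <- c("texture_P120", "texture_P280", "choice", "value",
             "whisk_coupled", "lick_coupled", "sound", "touch_nonselective",
             "nonselective")
  stopifnot(all(names(n_per_class) %in% valid),
            response_amp >= 0, noise_sd > 0,
            kernel_decay_s > kernel_rise_s, kernel_rise_s > 0)
  cls <- rep(names(n_per_class), n_per_class)
  n <- length(cls)
  jit <- withSeed(seed, stats::runif(n, 1 - amp_jitter, 1 + amp_jitter))
  data.frame(
    neuron_id = sprintf("neuron_%03d", seq_len(n)),
    true_class = cls,
    response_amp = ifelse(cls == "nonselective", 0, response_amp * jit),
    noise_sd = noise_sd,
    kernel_rise_s = kernel_rise_s,
    kernel_decay_s = kernel_decay_s,
    neuropil_gain = neuropil_gain,
    stringsAsFactors = FALSE
  )
}

#' Generate a pseudo-random stimulus sequence
#'
#' Each trial presents one of two textures with probability `p_go` for the
#' first (P120), subject to a run-length constraint: after
#' `max_consecutive` identical presentations the other texture is forced
#' (the disallowed label's probability mass is renormalised onto the
#' alternative at draw time).
#'
#' @param n number of trials.
#' @param p_go per-trial probability of `"P120"`.
#' @param max_consecutive longest permitted identical run.
#' @param seed RNG seed.
#' @return Character vector of `"P120"`/`"P280"` labels.
#' @export
generateStimulusSequence <- function(n, p_go = 0.5, max_consecutive = 4,
                                     seed = NULL) {
  stopifnot(n >= 1, p_go > 0, p_go < 1, max_consecutive >= 1)
  withSeed(seed, {
    u <- stats::runif(n)
    out <- character(n)
    run <- 0L
    last <- ""
    for (i in seq_len(n)) {
      draw <- if (u[i] < p_go) "P120" else "P280"
      if (run >= max_consecutive && draw == last) {
        draw <- if (last == "P120") "P280" else "P120"
      }
      if (draw == last) run <- run + 1L else run <- 1L
      last <- draw
      out[i] <- draw
    }
    out
  })
}

## Logistic learning schedule: per-trial probability of a correct choice.
agentSchedule <- function(n, agent) {
  t <- seq_len(n)
  ps <- agent$p_correct_start
  pe <- agent$p_correct_expert
  pre <- ps + (pe - ps) / (1 + exp(-agent$learning_slope *
                                     (t - agent$learning_midpoint)))
  if (is.na(agent$reversal_trial)) return(pre)
  rm_ <- agent$relearning_midpoint
  if (is.na(rm_)) rm_ <- agent$reversal_trial + 450
  post <- ps + (pe - ps) / (1 + exp(-agent$learning_slope * (t - rm_)))
  ifelse(t < agent$reversal_trial, pre, post)
}

## Trial at which the post-reversal schedule crosses `p` (closed form);
## NA when the asymptote never reaches p.
scheduleCrossing <- function(agent, p = 0.70) {
  ps <- agent$p_correct_start; pe <- agent$p_correct_expert
  if (pe <= p) return(NA_real_)
  if (ps >= p) return(agent$reversal_trial)
  rm_ <- agent$relearning_midpoint
  if (is.na(rm_)) rm_ <- agent$reversal_trial + 450
  rm_ - log((pe - ps) / (p - ps) - 1) / agent$learning_slope
}

#' Simulate the behaving agent
#'
#' Rolls out the learning agent over a stimulus sequence: each trial the
#' agent makes the correct choice with the scheduled probability (lick on
#' the currently rewarded texture, withhold otherwise), lick and whisk event
#' times are drawn, and the outcome is scored with [scoreTrial()] — the same
#' code path used for real trial tables.
#'
#' @param stimuli character vector of stimulus labels.
#' @param rewarded character vector, the rewarded stimulus per trial (the
#'   contingency epoch); same length as `stimuli`.
#' @param agent [agentParams()] list.
#' @param config [simConfig()] list (trial layout and timing).
#' @param seed RNG seed.
#' @return data.frame with one row per trial: `trial_id`, `stimulus`,
#'   `rewarded_stimulus`, `outcome`, `reaction_time_s`, `n_licks_texture`,
#'   `lick_rate_texture`, `whisk_rate_texture`, `relearning` (logical:
#'   within the post-reversal relearning window), and list-columns
#'   `lick_times`, `whisk_times` (seconds from trial start).
#' @export
simulateAgent <- function(stimuli, rewarded, agent = agentParams(),
                          config = simConfig(), seed = NULL) {
  n <- length(stimuli)
  if (length(rewarded) != n) {
    stop("stimuli and rewarded contingency must have equal length")
  }
  lay <- config$layout
  tOn <- lay$baseline_s + lay$cue_s + lay$delay_s
  tOff <- tOn + lay$texture_s
  tEnd <- tOff + lay$post_s
  p <- agentSchedule(n, agent)
  withSeed(seed, {
    correct <- stats::runif(n) < p
    go <- stimuli == rewarded
    lick <- ifelse(go, correct, !correct)
    lickTimes <- vector("list", n)
    whiskTimes <- vector("list", n)
    rt <- rep(NA_real_, n)
    outcome <- character(n)
    maxRT <- lay$texture_s - 0.1
    pmaxRT <- stats::pgamma(maxRT - 0.1, agent$lick_latency_shape,
                            agent$lick_latency_rate)
    for (i in seq_len(n)) {
      lt <- numeric(0)
      ## impulsive licking outside the texture window, all trials
      nPre <- stats::rpois(1, agent$lick_rate_nogo * tOn)
      if (nPre > 0) lt <- stats::runif(nPre, 0, tOn)
      if (lick[i]) {
        u <- stats::runif(1, 0, pmaxRT)
        rt[i] <- 0.1 + stats::qgamma(u, agent$lick_latency_shape,
                                     agent$lick_latency_rate)
        first <- tOn + rt[i]
        span <- (tOff + 0.8) - first
        nMore <- stats::rpois(1, agent$lick_rate_go * span)
        more <- if (nMore > 0) sort(stats::runif(nMore, first, first + span))
                else numeric(0)
        lt <- c(lt, first, more)
      } else {
        nPost <- stats::rpois(1, agent$lick_rate_nogo * (tEnd - tOff))
        if (nPost > 0) lt <- c(lt, stats::runif(nPost, tOff, tEnd))
      }
      lt <- sort(pmin(lt, tEnd - 1e-6))
      wr <- max(0.5, stats::rnorm(1, agent$whisk_rate_mean,
                                  agent$whisk_rate_sd))
      nW <- stats::rpois(1, wr * tEnd)
      wt <- if (nW > 0) sort(stats::runif(nW, 0, tEnd)) else numeric(0)
      lickTimes[[i]] <- lt
      whiskTimes[[i]] <- wt
      outcome[i] <- scoreTrial(stimuli[i], rewarded[i], lt, c(tOn, tOff))
      ## reaction time is defined whenever a lick lands in the texture window
      inWin <- lt[lt >= tOn & lt < tOff]
      rt[i] <- if (length(inWin)) inWin[1] - tOn else NA_real_
    }
    relearnEnd <- if (is.na(agent$reversal_trial)) NA_real_ else
      scheduleCrossing(agent, 0.70)
    relearning <- if (is.na(agent$reversal_trial)) rep(FALSE, n) else
      seq_len(n) >= agent$reversal_trial &
        (is.na(relearnEnd) | seq_len(n) <= relearnEnd)
    df <- data.frame(
      trial_id = seq_len(n),
      stimulus = stimuli,
      rewarded_stimulus = rewarded,
      outcome = outcome,
      reaction_time_s = rt,
      n_licks_texture = vapply(lickTimes, function(x)
        sum(x >= tOn & x < tOff), integer(1)),
      relearning = relearning,
      stringsAsFactors = FALSE
    )
    df$lick_rate_texture <- df$n_licks_texture / lay$texture_s
    df$whisk_rate_texture <- vapply(whiskTimes, function(x)
      sum(x >= tOn & x < tOff), integer(1)) / lay$texture_s
    df$lick_times <- I(lickTimes)
    df$whisk_times <- I(whiskTimes)
    df
  })
}

## Double-exponential indicator kernel sampled at the frame rate, peak 1.
calciumKernel <- function(rise_s, decay_s, frame_rate, n_tau = 6) {
  t <- seq(0, n_tau * decay_s, by = 1 / frame_rate)
  h <- exp(-t / decay_s) - exp(-t / rise_s)
  h / max(h)
}

#' Simulate two-channel fluorescence traces
#'
#' Builds per-neuron underlying event rates conditioned on each neuron's
#' ground-truth class and the behavioural record, draws spikes, convolves
#' them with a rise/decay indicator kernel, and assembles measured,
#' neuropil and control fluorescence channels. The control channel carries
#' only noise and is statistically independent of behaviour.
#'
#' Class models (driving condition for the evoked rate during the texture
#' window unless stated):
#' \describe{
#'   \item{texture_P120 / texture_P280}{their texture is presented}
#'   \item{choice}{the animal licks during the texture window}
#'   \item{value}{the presented texture is the one the neuron's slowly
#'     updated contingency belief holds to be rewarded; amplitude scales
#'     with the belief, so selectivity degrades and reverses after the
#'     contingency reversal}
#'   \item{whisk_coupled / lick_coupled}{rate proportional to the
#'     instantaneous whisking / licking rate over the whole trial}
#'   \item{sound}{the auditory cue window}
#'   \item{touch_nonselective}{any texture presentation}
#'   \item{nonselective}{baseline rate only}
#' }
#' Value-class neurons additionally express an error-history boost: on hit
#' trials preceded by a false alarm during the relearning window their
#' evoked amplitude is multiplied by `1 + eh_boost`.
#'
#' @param trials trial table from [simulateAgent()].
#' @param neurons data.frame from [neuronCohort()].
#' @param config [simConfig()].
#' @param seed RNG seed.
#' @return A [CalciumSession-class] with assays `activity`, `control`,
#'   `neuropil` and the ground-truth table.
#' @export
simulateTraces <- function(trials, neurons, config = simConfig(),
                           seed = NULL) {
  stopifnot(nrow(neurons) > 0)
  lay <- config$layout
  fr <- config$frame_rate
  trialDur <- sum(unlist(lay))
  nf <- floor(trialDur * fr)
  nT <- nrow(trials)
  tWithin <- (seq_len(nf) - 0.5) / fr
  bounds <- cumsum(unlist(lay))
  phaseOf <- cut(tWithin, c(0, bounds),
                 labels = c("baseline", "cue", "delay", "texture", "post"),
                 right = FALSE)
  phase <- rep(as.character(phaseOf), nT)
  frTrial <- rep(trials$trial_id, each = nf)
  nFrames <- nf * nT
  dt <- 1 / fr

  texOn <- bounds["delay_s"]
  isTex <- as.character(phaseOf) == "texture"
  isCue <- as.character(phaseOf) == "cue"

  ## behaviour rate traces on the frame grid (same estimator as analysis)
  whiskRate <- numeric(nFrames)
  lickRate <- numeric(nFrames)
  for (i in seq_len(nT)) {
    idx <- ((i - 1) * nf + 1):(i * nf)
    whiskRate[idx] <- eventRateTrace(trials$whisk_times[[i]], tWithin)
    lickRate[idx] <- eventRateTrace(trials$lick_times[[i]], tWithin)
  }

  ## contingency belief (P120 rewarded), updated from the reward history
  b <- numeric(nT)
  bi <- 0.5
  for (i in seq_len(nT)) {
    bi <- bi + config$belief_alpha *
      ((trials$rewarded_stimulus[i] == "P120") - bi)
    b[i] <- bi
  }

  prevOutcome <- c(NA, trials$outcome[-nT])
  postFAHit <- trials$outcome == "hit" & !is.na(prevOutcome) &
    prevOutcome == "FA"
  licked <- trials$n_licks_texture > 0

  seeds <- childSeeds(seed %||% 1L, nrow(neurons) + 1L)

  baseRate <- 0.2
  nN <- nrow(neurons)
  act <- matrix(0, nN, nFrames)
  ctrl <- matrix(0, nN, nFrames)
  npilMat <- matrix(0, nN, nFrames)

  ## shared slow neuropil fluctuation (common across neurons)
  npil <- withSeed(seeds[nN + 1L], {
    as.numeric(stats::filter(stats::rnorm(nFrames), 0.98,
                             method = "recursive"))
  })
  npil <- npil / stats::sd(npil)

  for (j in seq_len(nN)) {
    spec <- neurons[j, ]
    ## per-trial evoked amplitude (events/s) during the driving window
    ampTrial <- switch(spec$true_class,
      texture_P120 = spec$response_amp * (trials$stimulus == "P120"),
      texture_P280 = spec$response_amp * (trials$stimulus == "P280"),
      choice = spec$response_amp * licked,
      value = spec$response_amp *
        ifelse(trials$stimulus == "P120", b, 1 - b),
      touch_nonselective = rep(spec$response_amp, nT),
      sound = rep(spec$response_amp, nT),
      rep(0, nT)
    )
    if (spec$true_class == "value" && config$eh_boost > 0) {
      boost <- postFAHit & trials$relearning
      ampTrial <- ampTrial * (1 + config$eh_boost * boost)
    }
    win <- if (spec$true_class == "sound") isCue else isTex
    rate <- rep(baseRate, nFrames)
    rate <- rate + rep(ampTrial, each = nf) * rep(as.numeric(win), nT)
    if (spec$true_class == "whisk_coupled") {
      rate <- rate + spec$response_amp * whiskRate / 6
    }
    if (spec$true_class == "lick_coupled") {
      rate <- rate + spec$response_amp * lickRate / 4
    }
    withSeed(seeds[j], {
      spikes <- if (config$poisson_spikes) {
        stats::rpois(nFrames, rate * dt)
      } else {
        rate * dt
      }
      kern <- calciumKernel(spec$kernel_rise_s, spec$kernel_decay_s, fr)
      sig <- config$spike_amp *
        as.numeric(stats::filter(spikes, kern, method = "convolution",
                                 sides = 1))
      sig[is.na(sig)] <- 0
      f0 <- config$f0_level
      npilTrace <- 50 + config$npil_amp * npil +
        stats::rnorm(nFrames, 0, 2)
      act[j, ] <- f0 * (1 + sig) +
        spec$neuropil_gain * config$npil_amp * npil +
        f0 * stats::rnorm(nFrames, 0, spec$noise_sd)
      npilMat[j, ] <- npilTrace
      ctrl[j, ] <- f0 * (1 + stats::rnorm(nFrames, 0, spec$noise_sd))
    })
  }
  rownames(act) <- rownames(ctrl) <- rownames(npilMat) <- neurons$neuron_id
  CalciumSession(
    activity = act, control = ctrl, neuropil = npilMat,
    trials = trials, frameTrial = frTrial, framePhase = phase,
    frameRate = fr,
    metadata = list(texture_onset_s = unname(bounds["delay_s"]),
                    frames_per_trial = nf,
                    config = unclass(config)),
    groundTruth = neurons
  )
}

#' Simulate a full reversal-learning experiment
#'
#' Generates the stimulus sequence, the contingency epochs (P120 rewarded
#' before the reversal, P280 after), the behaving agent and the two-channel
#' traces for one subject, split into sessions of
#' `config$trials_per_session` trials.
#'
#' @param config [simConfig()].
#' @param agent [agentParams()]; `reversal_trial` defaults to the first
#'   trial after the pre-reversal sessions.
#' @param neurons [neuronCohort()] data.frame.
#' @param seed master RNG seed.
#' @param subject subject identifier stored in the metadata.
#' @return A [CalciumSession-class] covering all sessions, with
#'   `trials(x)$session_id` marking session blocks and
#'   `metadata(x)$reversal_trial` the first reversed trial.
#' @export
simulateExperiment <- function(config = simConfig(), agent = agentParams(),
                               neurons = neuronCohort(), seed = 1,
                               subject = "sim_subject") {
  nPre <- config$n_sessions_pre * config$trials_per_session
  nPost <- config$n_sessions_post * config$trials_per_session
  n <- nPre + nPost
  if (is.na(agent$reversal_trial)) agent$reversal_trial <- nPre + 1L
  if (is.na(agent$relearning_midpoint)) {
    agent$relearning_midpoint <- agent$reversal_trial + 450
  }
  seeds <- childSeeds(seed, 3)
  stimuli <- generateStimulusSequence(n, config$p_go, config$max_consecutive,
                                      seed = seeds[1])
  rewarded <- ifelse(seq_len(n) < agent$reversal_trial, "P120", "P280")
  trials <- simulateAgent(stimuli, rewarded, agent, config, seed = seeds[2])
  trials$session_id <- (trials$trial_id - 1L) %/% config$trials_per_session + 1L
  sess <- simulateTraces(trials, neurons, config, seed = seeds[3])
  md <- metadata(sess)
  md$subject <- subject
  md$reversal_trial <- agent$reversal_trial
  md$seed <- seed
  sess@metadata <- md
  sess
}

#' Simulate spontaneous-activity segments
#'
#' Generates normalised spontaneous traces for a cohort of neurons, with an
#' optional shared latent input added to the neurons of selected classes
#' (modelling increased co-fluctuation within a functional group).
#'
#' @param neurons [neuronCohort()] data.frame.
#' @param duration_s segment length, seconds.
#' @param shared_classes character vector of `true_class` values receiving
#'   the shared latent drive.
#' @param shared_amp event-rate amplitude of the shared drive, events/s.
#' @param config [simConfig()] (frame rate, spike amplitude).
#' @param seed RNG seed.
#' @return list with `dff` (neurons x frames matrix of normalised traces)
#'   and `truth` (the cohort table).
#' @export
simulateSpontaneous <- function(neurons, duration_s = 120,
                                shared_classes = character(),
                                shared_amp = 2, config = simConfig(),
                                seed = NULL) {
  fr <- config$frame_rate
  nFrames <- floor(duration_s * fr)
  dt <- 1 / fr
  seeds <- childSeeds(seed %||% 1L, nrow(neurons) + 1L)
  latent <- withSeed(seeds[nrow(neurons) + 1L], {
    l <- as.numeric(stats::filter(stats::rnorm(nFrames), 0.9,
                                  method = "recursive"))
    pmax(l / stats::sd(l), 0)
  })
  dff <- matrix(0, nrow(neurons), nFrames,
                dimnames = list(neurons$neuron_id, NULL))
  for (j in seq_len(nrow(neurons))) {
    spec <- neurons[j, ]
    rate <- rep(0.3, nFrames)
    if (spec$true_class %in% shared_classes) {
      rate <- rate + shared_amp * latent
    }
    dff[j, ] <- withSeed(seeds[j], {
      spikes <- stats::rpois(nFrames, rate * dt)
      kern <- calciumKernel(spec$kernel_rise_s, spec$kernel_decay_s, fr)
      sig <- config$spike_amp *
        as.numeric(stats::filter(spikes, kern, method = "convolution",
                                 sides = 1))
      sig[is.na(sig)] <- 0
      sig + stats::rnorm(nFrames, 0, spec$noise_sd)
    })
  }
  list(dff = dff, truth = neurons)
}
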
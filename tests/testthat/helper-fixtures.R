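## Shared synthetic fixtures, built once per test run.
##
## The "small" experiment compresses learning into 5 sessions of 150 trials
## (logistic midpoints chosen so both expert criteria are reached) while
## keeping the default trial layout, noise level and class models, so that
## module tests run in seconds. Scale-sensitive properties are exercised at
## the generator's default scale inside the acceptance suite.

fixtureConfig <- function(...) {
  simConfig(n_sessions_pre = 2, n_sessions_post = 3,
            trials_per_session = 150, ...)
}

fixtureAgent <- function(reversal_trial = 301, relearning_midpoint = 400) {
  agentParams(learning_midpoint = 40, learning_slope = 0.08,
              reversal_trial = reversal_trial,
              relearning_midpoint = relearning_midpoint)
}

fixtureCohort <- function() {
  neuronCohort(n_per_class = c(texture_P120 = 2, texture_P280 = 1,
                               choice = 2, value = 2, whisk_coupled = 1,
                               lick_coupled = 1, nonselective = 4),
               seed = 3)
}

fixtureSession <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulateExperiment(fixtureConfig(), fixtureAgent(),
                                   fixtureCohort(), seed = 7)
    }
    cache
  }
})

fixturePrep <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- preprocessSession(fixtureSession())
    cache
  }
})

fixtureResponses <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- trialResponses(fixturePrep()$dff$dff, fixtureSession())
    }
    cache
  }
})

fixturePhases <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- learningPhases(trials(fixtureSession()), 301)
    }
    cache
  }
})

## Brute-force pairwise (Mann-Whitney) AUC oracle: P(a > b) + 0.5 P(a = b).
pairwiseAUC <- function(a, b) {
  mean(outer(a, b, ">")) + 0.5 * mean(outer(a, b, "=="))
}

## A tiny hand-built session: `n_trials` trials whose dff is fully
## controlled by the caller via `dffFun(trial, phase_labels)`.
tinySession <- function(n_trials = 6, n_neurons = 2, frame_rate = 10,
                        stimuli = rep(c("P120", "P280"),
                                      length.out = n_trials)) {
  nf <- 40  # 4 s per trial at 10 Hz
  phase <- rep(c(rep("baseline", 10), rep("cue", 2), rep("delay", 5),
                 rep("texture", 20), rep("post", 3)), n_trials)
  ft <- rep(seq_len(n_trials), each = nf)
  trials <- data.frame(
    trial_id = seq_len(n_trials), session_id = 1L,
    stimulus = stimuli,
    rewarded_stimulus = "P120",
    outcome = ifelse(stimuli == "P120", "hit", "CR"),
    n_licks_texture = ifelse(stimuli == "P120", 3L, 0L),
    reaction_time_s = ifelse(stimuli == "P120", 0.4, NA)
  )
  trials$lick_times <- I(lapply(seq_len(n_trials), function(i)
    if (stimuli[i] == "P120") c(2.1, 2.5, 3.0) else numeric(0)))
  trials$whisk_times <- I(lapply(seq_len(n_trials), function(i)
    seq(0.1, 3.9, by = 0.5)))
  act <- matrix(100, n_neurons, nf * n_trials)
  CalciumSession(activity = act, control = act, neuropil = NULL,
                 trials = trials, frameTrial = ft, framePhase = phase,
                 frameRate = frame_rate,
                 metadata = list(texture_onset_s = 1.7,
                                 frames_per_trial = nf))
}
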
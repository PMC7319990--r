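# revroc

ROC-based stimulus selectivity of cortical neurons across reversal learning.

`revroc` analyses trial-structured two-photon calcium imaging recorded while
an animal performs a Go/No-go texture discrimination and subsequent reversal
learning. It answers, per neuron, the questions that drive this kind of
experiment: is the neuron selective for one of the two textures; does that
selectivity survive, appear, vanish or invert when the reward contingency is
reversed; does the neuron's signal track the stimulus, the upcoming choice,
or the current reward *value* of the stimulus; does its activity predict
whisking or licking; and does any neural signal anticipate the behavioural
improvement during relearning?

## The statistics at its core

* **Discrimination index (DI)** — from an ROC comparing the trial responses
  (mean ΔF/F₀ over the 2-s texture window) on P120 vs. P280 trials:
  `DI = (AUC − 0.5) × 2 ∈ [−1, 1]`, positive when P120 evokes larger
  responses. Thresholds are spaced linearly from the minimum to the maximum
  of the pooled responses. Significance by permutation: trial labels
  shuffled 10,000 times, two-sided decision at the 2.5th–97.5th null
  percentiles. The **choice index (CI)** is the same construction for lick
  vs. no-lick trials.
* **Learning classes** — from the pre- and post-reversal expert DIs:
  gained / lost / remained / reversed / non-selective; reversed neurons
  subdivide into **choice** (CI significant with one sign through all
  phases) and **value** (CI collapses or flips in the post-reversal naive
  phase).
* **Behavioural decoding** — regression forests (128 trees, minimum node
  size 2, `mtry = max(1, ⌊p/3⌋)`) predict whisking/licking rates from 11
  time-lagged 100-ms bins of nonnegatively deconvolved firing rates, with
  5-fold cross-validation over trials; a neuron is predictive when its
  observed-vs-predicted Pearson correlation exceeds the mean + 5 SD of the
  same analysis run on an activity-independent control channel.
* **Error history** — per neuron, on a trial axis realigned to the 70%
  expert criterion:
  `EH(t) = (R̄_hit(post FA) − R̄_hit(post hit)) / R̄_hit` over a sliding
  201-trial window, with 95% bounds from 1,000 within-window permutations
  of the hit responses.

A synthetic-session generator (`simulateExperiment()`) produces complete
experiments — stimulus sequences (50% per texture, at most 4 consecutive
repeats), a logistic learning agent that collapses to chance at the reversal
and recovers, and class-conditioned two-channel calcium traces with ground
truth — so the whole chain is testable end to end.

## Worked example

```r
library(revroc)

cfg    <- simConfig(n_sessions_pre = 2, n_sessions_post = 3,
                    trials_per_session = 150)
agent  <- agentParams(learning_midpoint = 40, learning_slope = 0.08,
                      reversal_trial = 301, relearning_midpoint = 400)
cohort <- neuronCohort(n_per_class = c(texture_P120 = 2, choice = 2,
                                       value = 2, nonselective = 2),
                       seed = 3)
session <- simulateExperiment(cfg, agent, cohort, seed = 11)
session
#> CalciumSession: 8 neurons x 48750 frames @ 11.5 Hz
#>   750 trials in 5 session(s); outcomes: CR=300 FA=71 hit=300 miss=79
#>   ground truth: choice=2 nonselective=2 texture_P120=2 value=2

sessionPerformance(trials(session))
#>   session_id n_trials hit_rate fa_rate performance
#> 1          1      150    0.859   0.241        80.7
#> 2          2      150    0.829   0.125        85.3
#> 3          3      150    0.637   0.343        64.7
#> 4          4      150    0.866   0.118        87.3
#> 5          5      150    0.776   0.135        82.0
```

Performance collapses in session 3 — the first after the reversal at trial
301 — and recovers above the 70% expert criterion. The three learning
phases and the classification:

```r
phases    <- learningPhases(trials(session), reversal_trial = 301)
prep      <- preprocessSession(session)          # neuropil, detrend, dF/F0
responses <- trialResponses(prep$dff$dff, session)
cls <- classifyNeurons(responses, trials(session), phases,
                       n_perm = 1000, seed = 5)
cbind(truth = groundTruth(session)$true_class,
      cls[, c("learning_class", "subclass")],
      round(cls[, c("di_pre", "di_post", "ci_naive")], 2))
#>          truth learning_class subclass di_pre di_post ci_naive
#> 1 texture_P120       remained     none   0.99    0.97    -0.29
#> 2 texture_P120       remained     none   1.00    0.99    -0.46
#> 3       choice       reversed   choice   0.66   -0.74     0.99
#> 4       choice       reversed   choice   0.64   -0.63     0.98
#> 5        value       reversed    value   0.39   -0.34    -0.05
#> 6        value       reversed    value   0.47   -0.35    -0.05
#> 7 nonselective  non_selective     none  -0.04   -0.03     0.04
#> 8 nonselective  non_selective     none   0.08    0.05     0.09
```

Texture neurons keep their preference (`remained`, DI ≈ 1 in both expert
phases). Choice and value neurons both invert their DI (`reversed`), and the
naive-phase CI separates them: choice neurons keep predicting the lick
(ci_naive ≈ 0.99) while value neurons lose their choice signal
(ci_naive ≈ 0). `runPipeline()` chains all stages — preprocessing,
behaviour, selectivity, classification, decoding, error history — and writes
the stage CSVs plus a JSON summary with config and seeds.

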
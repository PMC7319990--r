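---
title: "Tracking stimulus selectivity across reversal learning with revroc"
author: "revroc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking stimulus selectivity across reversal learning with revroc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(revroc)
```

## The analysis problem

Head-fixed mice can learn a Go/No-go texture discrimination: licking during
presentation of a rewarded sandpaper (P120) earns water, licking for the
non-rewarded sandpaper (P280) earns a time-out. After the animal becomes
expert, the reward contingency can be reversed, forcing relearning. Two-photon
calcium imaging through this whole trajectory yields, per neuron, a
fluorescence trace of an activity-dependent indicator (GCaMP6s-like) plus an
activity-independent fluorophore (mRuby2-like) that reports measurement noise,
and, per trial, a behavioural record (stimulus, lick and whisk events,
outcome).

`revroc` implements the analysis chain that turns those inputs into
statements about single-neuron function: how selective is each neuron for the
two textures, does that selectivity track the stimulus, the animal's choice,
or the current reward value of the stimulus, and does any neural signal
anticipate the behavioural improvement during relearning? Because the
original imaging data are not bundled, the package ships a fully specified
synthetic-session generator with ground-truth neuron classes; every statistic
runs identically on real or simulated sessions.

## Trace preprocessing

The fixed preprocessing order is **neuropil correction, per-trial
detrending, then normalisation**:

1. `neuropilCorrect()`: \(F(t) = F_{measured}(t) - r \cdot F_{neuropil}(t)\)
   with \(r = 0.7\) by default.
2. `detrendTrial()`: the 8th percentile of each trial's trace is subtracted,
   each trial independently. One percentile definition is used everywhere in
   the package: linear interpolation between order statistics
   (`stats::quantile` type 7). Discontinuities at trial boundaries are
   permitted; the subtraction is a per-trial offset only.
3. `computeDFF()`: \(\Delta F/F_0 = (F - F_0)/F_0\) in one of two dialects.
   For task sessions, \(F_0\) is per neuron the *median across trials* of the
   mean baseline fluorescence over the 1-s pre-stimulus period of each trial.
   For stimulation and spontaneous recordings, \(F_0\) is the 30th percentile
   of each trial's trace, per neuron-trial. Any neuron-trial with
   \(F_0 \le 0\) is masked (`NA`) and propagates as missing, never clipped to
   avoid infinities.

Savitzky–Golay smoothing (`smoothDisplay()`, 2nd order, 500-ms span rounded
to an odd frame count) exists for display only; no statistic in the package
consumes the smoothed trace. At the trace boundaries the fitting window
shrinks rather than padding with fabricated samples.

Whether detrending precedes or follows neuropil subtraction is an ordering
the upstream protocol states only implicitly; we subtract neuropil first and
the order is fixed and tested.

### Spike inference

`inferSpikeRates()` performs fast nonnegative deconvolution under an AR(1)
transient model. After background subtraction (global or per-trial 8th
percentile), the denoised trace \(c\) is the least-squares fit to the input
subject to \(c_t \ge \gamma c_{t-1}\) and \(c \ge 0\), solved by a
pool-adjacent-violators pass; the inferred rate is the nonnegative innovation
\(s_t = c_t - \gamma c_{t-1}\). The AR coefficient defaults to
\(\gamma = e^{-1/(\tau f)}\) with \(\tau = 1.5\) s and \(f = 11.5\) Hz, and is
exposed because the value used by any particular indicator/zoom combination
is an empirical choice. Trials of all neurons of a subject are concatenated
before inference so that absolute activity levels remain comparable across
neurons. An indicator-saturation unmixing (hyperbolic in \(\Delta F/F_0\),
with the indicator's dissociation constant, 144 nM, recorded alongside)
is available but off by default; none of the downstream statistics depend on
it. The guarantee we test is the round trip: reconvolving the inferred rates
with the AR(1) kernel reproduces the denoised trace, and on simulated
transients the residual variance stays below the injected noise variance.

### Response onsets

`responseOnset()` averages hit-trial \(\Delta F/F_0\) aligned either to the
texture onset or to the first lick and reports the time at which the average
first reaches baseline plus half of its peak amplitude. The peak is taken
over the texture-presentation span only, to avoid reward-period transients;
an average that never exceeds baseline noise (mean + 2 SD of the pre-event
samples) yields a flagged `NA`. For lick alignment the search window starts
0.5 s before the event, because stimulus-locked activity rises before the
lick.

## Behavioural metrics

`scoreTrial()` scores hit / miss / FA / CR from the stimulus, the current
contingency and the lick events, including the anti-compulsive-licking rule:
a hit additionally requires a 2-fold increase of the texture-window lick rate
over the pre-stimulus baseline rate. Hit rate is
\(N_{hit}/(N_{hit}+N_{miss})\), FA rate \(N_{FA}/(N_{FA}+N_{CR})\), and
performance the percentage of correct trials (hits + CRs), over sessions or
a 200-trial sliding window (`rollingCurve()`; windows are full and
center-labelled, partial edge windows are dropped).

A subject is expert from the first pair of consecutive sessions at
\(\ge 70\%\) correct (`detectExpertCriterion()`). Because criterion-realigned
analyses need trial resolution while the criterion itself has session
resolution, `criterionTrial()` anchors \(t = 0\) at the first trial within
the criterion sessions whose rolling 200-trial performance reaches 70%.

`detectLearningOnset()` finds the last pre-criterion trial at which the 95%
bands of the across-subject mean hit rate and FA rate become and remain
disjoint. The band construction is a design choice the upstream protocol
leaves open: we bootstrap over subjects (percentile intervals, default 1,000
resamples) and require the separation to be sustained through the criterion
to ignore single-point crossings. The same band machinery is shared with the
error-history divergence detector, so the two "arrowheads" are comparable by
construction.

Median splits of hit trials by texture-window whisking or licking rate
(`splitByBehaviorRate()`) assign ties to the low set — a deterministic,
documented rule. Event rates everywhere come from one estimator
(`eventRateTrace()`): events counted in a centered 100-ms sliding window,
normalised per second; the simulator uses the same code path as the
analysis.

## Selectivity indices

The discrimination index of a neuron compares its trial responses (mean
\(\Delta F/F_0\) over the 2-s texture window, `trialResponses()`) on P120
versus P280 trials through an ROC analysis:

\[ DI = (AUC - 0.5) \times 2 \in [-1, 1], \]

positive when P120 evokes the larger responses. The ROC curve is built by
sweeping threshold levels spaced as a linear function from the minimum to the
maximum of the pooled responses and plotting the fraction of P120 trials
against the fraction of P280 trials whose response exceeds each threshold
(`rocAUC()`). Choices the protocol leaves open, fixed and tested here:
1,000 threshold levels by default; "exceeds" is strict, so ties at a
threshold fall below it; endpoints (0,0) and (1,1) are appended before
trapezoidal integration. An oracle-equivalence test guards these choices:
on random data the linear-threshold AUC differs from the pairwise
Mann–Whitney AUC by at most \(1/n_{thresholds}\) plus a tie term.

Significance comes from a permutation test (`permutationTest()`): the trial
labels are shuffled (sampling without replacement) 10,000 times and the
observed index is significant when outside the 2.5th–97.5th percentile
interval of the null. Each neuron draws its own child seed from a master
seed, so results are reproducible and independent of evaluation order. The
choice index (CI) is the identical construction comparing lick versus
no-lick trials, with the same permutation count.

`rollingIndex()` evaluates either index over a sliding window of 100 trials
every 5 trials. Windows with fewer than 5 trials of either label yield a
flagged missing value — an AUC with a nearly empty side is unstable, and the
threshold is documented rather than silent. Per-window permutation
significance is optional (`n_perm = 0` skips it) because the rolling series
is descriptive; phase-level inference always uses the full permutation test.
`signAlignToPre()` maps post-reversal indices onto each neuron's pre-reversal
preference so that population averages read as "same preference" (positive)
versus "reversed preference" (negative).

## Neuron classification

Before training, neurons are categorised from a stimulation session:
`categorizeStimulusResponse()` compares 1-s pre- versus post-stimulus window
means across trials with a two-sided paired t-test at the 5% threshold, run
separately per stimulus and per channel. The control channel audits
artefacts: its positives must stay at the nominal rate. Whisk- and
lick-predictive categories come from the decoding stage below; the flags are
reported side by side without forced exclusivity.

Across learning phases — pre-reversal expert, post-reversal naive (from the
reversal to the trial-level criterion anchor), post-reversal expert — each
neuron receives one learning class from its two expert-phase DIs
(`assignLearningClass()`): *non-selective*, *gained*, *lost*, *remained*
(both significant, same sign) or *reversed* (both significant, opposite
sign). "Selective" always means permutation-significant, never an
effect-size cut. Expert-phase DIs pool the trials of that phase's sessions
rather than averaging per-session indices — more trials per ROC, and the
interpretation is recorded here. Reversed neurons subdivide on their CIs in
all three phases (`subdivideReversed()`): *choice* neurons keep a
significant CI of one sign throughout (the naive phase treated as a single
pooled block); *value* neurons lose or flip their CI in the naive phase.

## Behavioural decoding

`decodeBehavior()` asks, per neuron, whether its inferred firing rates
predict whisking and/or licking. Eleven 100-ms bins of inferred rate,
centred on zero lag (\(\pm\)500 ms), form the predictor vector per frame
(`buildLaggedDesign()`). Because 100-ms bins do not tile 11.5-Hz frames
evenly, bins are defined in time and filled by fractional-overlap weighting,
validated against a windowed-sum oracle. Lag windows never borrow frames
across trial boundaries; out-of-trial contributions are zero — conservative,
and documented, since concatenated trials make boundary frames ambiguous.

Regression forests use fixed, contractual settings: 128 trees, minimum node
size 2, `mtry = max(1, floor(p/3))`, impurity importance (recorded, unused).
Cross-validation is 5-fold over *trials*, never frames, so out-of-fold
predictions cover every trial without leakage (`fitDecoderCV()`). Decoding
accuracy is the Pearson correlation between observed and predicted rates
(`predictionPower()`), and a neuron is predictive when its correlation
exceeds the mean + 5 SD of the correlations obtained from the identical
analysis of the control channel (`controlThreshold()`). We compute the
threshold per behaviour (whisk and lick separately); pooling is the
plausible alternative, and with the control channel carrying no signal the
two choices differ negligibly.

## Error history

For each neuron, hit trials are conditioned on their immediate predecessor
(`partitionHits()`): post-FA hits, post-hit hits, and other hits (which
enter only the all-hit mean). On the criterion-realigned axis the error
history over an inclusive 201-trial window \(t-100..t+100\) is

\[ EH(t) = \frac{\bar R_{hit(post\,FA)} - \bar R_{hit(post\,hit)}}
                {\bar R_{hit}} . \]

The printed span "window of 200 trials" and the notation \(t-100:t+100\)
disagree by one trial; we follow the notation (201 trials, symmetric).
Confidence bounds come from permuting all hit responses among the hit
positions within each window 1,000 times and taking the 2.5th/97.5th
percentiles (`errorHistoryNull()`). The statistic is scale invariant and
antisymmetric in the two conditioned sets; both properties are tested.

`responseDivergenceTrial()` applies the shared band machinery to the post-FA
and post-hit response curves across subjects and reports the last
pre-criterion trial of sustained separation. On simulated cohorts in which
only value neurons carry a post-FA response boost during relearning, this
divergence precedes the behavioural learning onset — the ordering the
analysis is designed to expose.

One desk-scale caveat, handled explicitly: with hundreds of overlapping
windows per neuron, "significant anywhere before the criterion" saturates
under multiplicity. `significantFractionByClass()` therefore also offers a
`window_fraction` statistic (mean fraction of significant windows per
neuron), which is what the package's own acceptance checks use, restricted
to the relearning span where the boost is programmed.

Spontaneous co-fluctuation analysis (`cofluctuation()`, `comparePhases()`)
is plain pairwise Pearson correlation of normalised traces on task-free
segments, with zero-variance pairs flagged.

## The synthetic-session generator

`simulateExperiment()` produces a complete reversal experiment for one
subject: stimulus sequence, learning agent, and two-channel traces with
ground truth. Its defaults are the study conditions, not tuning knobs:

* **Task**: 50% per-texture probability with at most 4 consecutive identical
  presentations (implemented by renormalising the disallowed label's mass
  onto the alternative at draw time, since the original sampler is not
  stated); 1-s baseline, 0.2-s cue, 0.5-s delay, 2-s texture; 11.5-Hz
  frames. The post-stimulus period defaults to 2 s, making the trial cadence
  (~10 s with inter-trial machinery folded in) comparable to the task's
  ~6 trials/min; a much shorter trial would exaggerate indicator carryover
  between consecutive trials relative to the real recordings.
* **Agent**: the probability of a correct choice is logistic in trial index
  (the simplest monotone ramp with the observed shape), rising from chance
  toward 0.82 — the expert performance plateau — collapsing at the reversal
  and recovering along a second logistic (default midpoint 450 trials after
  reversal). Lick times (gamma first-lick latency, Poisson lick train) and
  whisk times (per-trial Gaussian rate, Poisson events) are drawn per trial,
  and outcomes are scored by the *analysis* scorer, not by the generator.
* **Neurons**: each class drives an underlying event rate (texture-,
  choice-, value-, whisk-, lick-, sound-conditioned, or none); spikes are an
  inhomogeneous Poisson process (4 sessions of 250 trials per phase by
  default), convolved with a rise/decay kernel (0.2 s / 1.5 s, GCaMP6s-like
  simulator defaults, not claims about the indicator), scaled at 0.2
  \(\Delta F/F_0\) per event, plus a shared slow neuropil fluctuation and
  Gaussian noise (SD 0.1 \(\Delta F/F_0\) per frame — a realistic
  single-frame noise level for somatic GCaMP imaging). The control channel
  carries noise only. Value-class amplitudes multiply a contingency belief
  updated from the reward history with rate 0.002/trial, so post-reversal
  naive selectivity degrades and reverses by construction; the programmed
  error-history boost (+50% on post-FA hits) is confined to value neurons
  and to the relearning window. `poisson_spikes = FALSE` yields noiseless
  deterministic responses for exact-recovery tests.

What the generator does **not** emulate: photon statistics, movement
artefacts, correlated population noise beyond the shared neuropil, drifting
baselines across sessions, and reaction-time dependence on difficulty.
Passing tests on synthetic sessions therefore demonstrate the correctness
and calibration of the *analysis*, not the biology of any particular
dataset.

## Numerical choices and problem sizes

* Percentiles: type-7 linear interpolation, everywhere.
* Degenerate ROC inputs (all pooled responses identical) return AUC 0.5,
  flagged; zero-variance paired differences are "not responsive", flagged;
  zero-variance prediction targets yield flagged `NA` correlations.
* Seeds: every stochastic stage derives child seeds (below \(2^{31}\)) from
  one master seed; identical seeds give byte-identical outputs.
* Test problem sizes: module tests run a compressed experiment (5 sessions
  of 150 trials, 13 neurons); calibration checks use 2,000 null neurons /
  windows with 300–1,000 permutations; the cross-subject ordering check uses
  three simulated subjects at the default scale (2,000 trials each). These
  sizes are the package's choices for routine verification; all statistics
  accept full-size inputs unchanged.

## Known limitations

* The session container is a plain-text directory (JSON + CSV) — easy to
  inspect and diff, lossless for the package's own round trips, but not a
  storage-efficient format for hour-long recordings.
* The learning-onset and divergence detectors bootstrap over subjects; with
  very few subjects the bands are optimistic and spurious separations are
  possible, so cohort analyses should use several subjects.
* The deconvolution is the plain AR(1) nonnegative solver without an
  explicit sparsity penalty; for low-SNR data a penalised variant would
  infer fewer, larger events.
* Pre-training categorisation and decoding operate on one session at a
  time; longitudinal identity of neurons across sessions is assumed given.
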
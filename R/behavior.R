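#' Score a single Go/No-go trial
#'
#' Outcomes follow the task rules: licking during presentation of the rewarded
#' texture yields a hit, provided the lick rate during the texture window is at
#' least twice the pre-stimulus baseline rate (the anti-compulsive-licking
#' rule); otherwise the trial is a miss. Licking during the non-rewarded
#' texture is a false alarm (FA); withholding is a correct rejection (CR).
#'
#' @param stimulus,rewarded_stimulus stimulus labels (e.g. `"P120"`,`"P280"`).
#' @param lick_times numeric vector of lick times, seconds from trial start.
#' @param texture_window length-2 numeric, `[onset, offset)` of the texture
#'   presentation in seconds from trial start.
#' @param baseline_lick_rate,texture_lick_rate licks/s in the pre-stimulus and
#'   texture windows. If `NULL`, both are computed from `lick_times` (baseline
#'   over `[0, onset)`).
#' @return One of `"hit"`, `"miss"`, `"FA"`, `"CR"`.
#' @export
scoreTrial <- function(stimulus, rewarded_stimulus, lick_times,
                       texture_window,
                       baseline_lick_rate = NULL, texture_lick_rate = NULL) {
  on <- texture_window[1]; off <- texture_window[2]
  lick_in_window <- any(lick_times >= on & lick_times < off)
  if (is.null(texture_lick_rate)) {
    texture_lick_rate <- sum(lick_times >= on & lick_times < off) / (off - on)
  }
  if (is.null(baseline_lick_rate)) {
    baseline_lick_rate <- if (on > 0) sum(lick_times < on) / on else 0
  }
  stopifnot(baseline_lick_rate >= 0, texture_lick_rate >= 0)
  go <- identical(stimulus, rewarded_stimulus)
  if (go) {
    if (lick_in_window && texture_lick_rate >= 2 * baseline_lick_rate) "hit"
    else "miss"
  } else {
    if (lick_in_window) "FA" else "CR"
  }
}

#' Hit rate, false-alarm rate and overall performance
#'
#' Hit rate is \eqn{N_{hit}/(N_{hit}+N_{miss})}, FA rate
#' \eqn{N_{FA}/(N_{FA}+N_{CR})}, and performance the percentage of correct
#' trials (hits + CRs). Rates with an empty denominator are `NA`.
#'
#' @param outcomes character vector of trial outcomes
#'   (`hit`/`miss`/`FA`/`CR`).
#' @return Named list with `hit_rate`, `fa_rate`, `performance` (percent).
#' @export
behaviorRates <- function(outcomes) {
  stopifnot(all(outcomes %in% c("hit", "miss", "FA", "CR")))
  nh <- sum(outcomes == "hit"); nm <- sum(outcomes == "miss")
  nf <- sum(outcomes == "FA"); nc <- sum(outcomes == "CR")
  list(
    hit_rate = if (nh + nm > 0) nh / (nh + nm) else NA_real_,
    fa_rate = if (nf + nc > 0) nf / (nf + nc) else NA_real_,
    performance = if (length(outcomes)) 100 * (nh + nc) / length(outcomes)
                  else NA_real_
  )
}

#' Rolling performance, hit-rate and FA-rate curves
#'
#' Computes the three behavioural series over a sliding window of full
#' `window` trials (default 200). Windows are center-labelled; partial edge
#' windows are dropped, so the first and last `floor(window/2)` entries are
#' `NA`. Windows lacking either trial type yield `NA` for the affected rate.
#'
#' @param trials data.frame with at least an `outcome` column, in
#'   chronological order.
#' @param window window length in trials.
#' @return data.frame with columns `trial`, `performance` (percent),
#'   `hit_rate`, `fa_rate`.
#' @export
rollingCurve <- function(trials, window = 200) {
  stopifnot(window >= 2)
  out <- trials$outcome
  n <- length(out)
  if (n < window) {
    warning("fewer trials than the window length; returning an empty curve")
    return(data.frame(trial = integer(), performance = numeric(),
                      hit_rate = numeric(), fa_rate = numeric()))
  }
  correct <- as.numeric(out %in% c("hit", "CR"))
  isGo <- out %in% c("hit", "miss")
  hit <- ifelse(isGo, as.numeric(out == "hit"), NA)
  fa <- ifelse(!isGo, as.numeric(out == "FA"), NA)
  data.frame(
    trial = seq_len(n),
    performance = 100 * rollMeanCentered(correct, window),
    hit_rate = rollMeanCentered(hit, window, na.rm = TRUE),
    fa_rate = rollMeanCentered(fa, window, na.rm = TRUE)
  )
}

#' Per-session performance summary
#'
#' @param trials trial table with `session_id` and `outcome` columns.
#' @return data.frame with one row per session: `session_id`, `n_trials`,
#'   `hit_rate`, `fa_rate`, `performance`.
#' @export
sessionPerformance <- function(trials) {
  sid <- unique(trials$session_id)
  res <- lapply(sid, function(s) {
    r <- behaviorRates(trials$outcome[trials$session_id == s])
    data.frame(session_id = s, n_trials = sum(trials$session_id == s),
               hit_rate = r$hit_rate, fa_rate = r$fa_rate,
               performance = r$performance)
  })
  do.call(rbind, res)
}

#' Detect the session-level expert criterion
#'
#' A subject is expert from the first session `s` such that sessions `s-1`
#' and `s` both reach at least `threshold` percent correct (default 70).
#'
#' @param performance numeric vector of per-session performance (percent), in
#'   chronological order.
#' @param threshold expert criterion in percent correct.
#' @return The (1-based) index of the second qualifying session, or
#'   `NA_integer_` if the criterion is never reached.
#' @export
detectExpertCriterion <- function(performance, threshold = 70) {
  ok <- performance >= threshold
  hit2 <- which(ok[-1] & ok[-length(ok)])
  if (!length(hit2)) return(NA_integer_)
  hit2[1] + 1L
}

#' Trial-level anchor for the expert criterion
#'
#' The session-level criterion has session resolution only; realigned
#' trial-axis analyses need a trial-resolution zero. The anchor is the first
#' trial, at or after the start of the first criterion session, whose rolling
#' `window`-trial performance reaches the threshold.
#'
#' @param trials trial table (chronological) with `session_id`, `outcome`.
#' @param criterion_session session index returned by
#'   [detectExpertCriterion()] (the second qualifying session).
#' @param window rolling window, trials.
#' @param threshold percent correct.
#' @return Trial index of the anchor, or `NA_integer_`.
#' @export
criterionTrial <- function(trials, criterion_session, window = 200,
                           threshold = 70) {
  if (is.na(criterion_session)) return(NA_integer_)
  sid <- unique(trials$session_id)
  firstSession <- sid[criterion_session - 1L]
  from <- min(which(trials$session_id == firstSession))
  curve <- rollingCurve(trials, window = window)
  cand <- which(!is.na(curve$performance) &
                  curve$performance >= threshold &
                  curve$trial >= from)
  if (!length(cand)) return(NA_integer_)
  curve$trial[cand[1]]
}

#' Realign a trial axis to the expert criterion
#'
#' @param trial_index integer vector of trial indices.
#' @param criterion_trial anchor trial (t = 0 after realignment).
#' @return `trial_index - criterion_trial`.
#' @export
realignToCriterion <- function(trial_index, criterion_trial) {
  if (is.na(criterion_trial)) {
    stop("criterion trial is undefined; cannot realign")
  }
  trial_index - criterion_trial
}

#' Detect the behavioural learning onset
#'
#' On the criterion-realigned axis, the learning onset is the last trial
#' before the criterion at which the 95% confidence bands of the
#' across-subject mean hit rate and FA rate become and remain disjoint.
#' Bands are bootstrap percentile intervals over subjects.
#'
#' @param curves list (one element per subject) of data.frames as returned by
#'   [rollingCurve()], each with an additional `t` column giving the
#'   criterion-realigned trial axis.
#' @param n_boot bootstrap resamples over subjects.
#' @param seed RNG seed for the bootstrap.
#' @param t_max upper end of the search axis (default 0, the criterion).
#' @return list with `onset` (realigned trial index or `NA`), `t` axis, and
#'   `hit`/`fa` band data.frames (`mean`, `lo`, `hi`).
#' @export
detectLearningOnset <- function(curves, n_boot = 1000, seed = NULL,
                                t_max = 0) {
  stopifnot(length(curves) >= 2)
  bands <- bootstrapBands(curves, c("hit_rate", "fa_rate"), n_boot, seed)
  onset <- bandSeparationPoint(
    bands$t,
    list(lo = bands$hit_rate$lo, hi = bands$hit_rate$hi),
    list(lo = bands$fa_rate$lo, hi = bands$fa_rate$hi),
    tMax = t_max
  )
  list(onset = onset, t = bands$t, hit = bands$hit_rate, fa = bands$fa_rate)
}

## Across-subject mean curves with bootstrap 95% percentile bands, on the
## union of the subjects' realigned axes. `vars` are column names present in
## every element of `curves`; each element must carry a `t` column.
bootstrapBands <- function(curves, vars, n_boot = 1000, seed = NULL) {
  tAxis <- sort(unique(unlist(lapply(curves, function(d) d$t))))
  mats <- lapply(vars, function(v) {
    m <- vapply(curves, function(d) {
      d[[v]][match(tAxis, d$t)]
    }, numeric(length(tAxis)))
    matrix(m, nrow = length(tAxis))
  })
  names(mats) <- vars
  nS <- length(curves)
  idx <- withSeed(seed, {
    matrix(sample.int(nS, nS * n_boot, replace = TRUE), nrow = nS)
  })
  out <- list(t = tAxis)
  qa <- function(z, p) {
    z <- z[is.finite(z)]
    if (!length(z)) NA_real_ else pctl(z, p)
  }
  for (v in vars) {
    m <- mats[[v]]
    boot <- vapply(seq_len(n_boot), function(b) {
      rowMeans(m[, idx[, b], drop = FALSE], na.rm = TRUE)
    }, numeric(length(tAxis)))
    mn <- rowMeans(m, na.rm = TRUE)
    mn[!is.finite(mn)] <- NA_real_
    out[[v]] <- data.frame(
      mean = mn,
      lo = apply(boot, 1, qa, p = 0.025),
      hi = apply(boot, 1, qa, p = 0.975)
    )
  }
  out
}

#' Median split of trials by a behavioural rate
#'
#' Splits trials into low and high sets at the median of the per-trial rate
#' (whisking or licking over the texture window). Ties at the median are
#' assigned to the low set.
#'
#' @param rates numeric per-trial rates.
#' @return list with integer index vectors `low` and `high`.
#' @export
splitByBehaviorRate <- function(rates) {
  if (length(rates) < 2) stop("need at least two trials for a median split")
  med <- stats::median(rates)
  list(low = which(rates <= med), high = which(rates > med))
}

#' Sliding-window event rate
#'
#' Converts a list of event times into an event-rate trace: the number of
#' events in a centered window (default 100 ms) around each query time,
#' normalised per second.
#'
#' @param event_times sorted numeric vector of event times, seconds.
#' @param at numeric vector of query times, seconds.
#' @param window_s window length, seconds.
#' @return numeric vector of rates (events/s), one per query time.
#' @export
eventRateTrace <- function(event_times, at, window_s = 0.1) {
  if (length(event_times) == 0) return(numeric(length(at)))
  stopifnot(!is.unsorted(event_times))
  lo <- findInterval(at - window_s / 2, event_times)
  hi <- findInterval(at + window_s / 2, event_times)
  (hi - lo) / window_s
}

#' Partition an experiment into learning phases
#'
#' Derives the three learning phases from the behavioural record of a full
#' reversal experiment: `pre_expert` (the two consecutive pre-reversal
#' sessions meeting the expert criterion), `post_naive` (trials from the
#' reversal up to, but excluding, the post-reversal trial-level criterion
#' anchor) and `post_expert` (from the anchor onward).
#'
#' @param trials chronological trial table with `session_id`, `outcome`.
#' @param reversal_trial index of the first trial after the contingency
#'   reversal.
#' @param window,threshold rolling window and criterion passed to
#'   [criterionTrial()].
#' @return data.frame with columns `phase`, `from`, `to` (inclusive trial
#'   spans), plus attribute `criterion_trial` (post-reversal anchor).
#' @export
learningPhases <- function(trials, reversal_trial, window = 200,
                           threshold = 70) {
  pre <- trials[seq_len(reversal_trial - 1L), ]
  post <- trials[seq(reversal_trial, nrow(trials)), ]
  perfPre <- sessionPerformance(pre)
  critPre <- detectExpertCriterion(perfPre$performance, threshold)
  if (is.na(critPre)) stop("pre-reversal expert criterion never reached")
  preSessions <- perfPre$session_id[c(critPre - 1L, critPre)]
  preIdx <- which(trials$session_id %in% preSessions)

  perfPost <- sessionPerformance(post)
  critPost <- detectExpertCriterion(perfPost$performance, threshold)
  if (is.na(critPost)) stop("post-reversal expert criterion never reached")
  anchorLocal <- criterionTrial(post, critPost, window = window,
                                threshold = threshold)
  anchor <- anchorLocal + reversal_trial - 1L
  ph <- data.frame(
    phase = c("pre_expert", "post_naive", "post_expert"),
    from = c(min(preIdx), reversal_trial, anchor),
    to = c(max(preIdx), anchor - 1L, nrow(trials))
  )
  attr(ph, "criterion_trial") <- anchor
  ph
}

#' Trials belonging to a phase
#'
#' @param phases data.frame from [learningPhases()].
#' @param phase phase name.
#' @return integer vector of trial indices.
#' @export
phaseTrials <- function(phases, phase) {
  row <- phases[phases$phase == phase, ]
  if (nrow(row) != 1) stop("unknown phase: ", phase)
  seq(row$from, row$to)
}
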
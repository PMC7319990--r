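#' Partition hit trials by the preceding outcome
#'
#' A hit enters `hit_post_FA` when the immediately preceding trial was a
#' false alarm and `hit_post_hit` when it was a hit; hits preceded by a
#' miss or correct rejection (or the first trial) fall into `hit_other` and
#' contribute only to the all-hit mean.
#'
#' @param outcomes chronological character vector of trial outcomes.
#' @return list of integer trial-index vectors: `hit_post_FA`,
#'   `hit_post_hit`, `hit_other`.
#' @export
partitionHits <- function(outcomes) {
  n <- length(outcomes)
  isHit <- outcomes == "hit"
  prev <- c(NA, outcomes[-n])
  list(
    hit_post_FA = which(isHit & !is.na(prev) & prev == "FA"),
    hit_post_hit = which(isHit & !is.na(prev) & prev == "hit"),
    hit_other = which(isHit & (is.na(prev) | !prev %in% c("FA", "hit")))
  )
}

## Window membership on the realigned axis: trials with t-100 <= t' <= t+100
## (inclusive 201-trial span).
ehWindowHalf <- function(window) {
  stopifnot(window >= 3)
  floor(window / 2)
}

#' Error-history curve of one neuron
#'
#' The error history at realigned trial `t` is the normalised difference
#' between the mean hit response following a false alarm and the mean hit
#' response following another hit, over the trial window `t-100 .. t+100`:
#' \deqn{EH(t) = \frac{\bar R_{hit(post FA)} - \bar R_{hit(post hit)}}
#'                    {\bar R_{hit}}}
#' It is defined only where the window contains at least one post-FA hit,
#' at least one post-hit hit, and a nonzero all-hit mean.
#'
#' @param responses numeric vector, one response (texture-window mean
#'   dF/F0) per trial; non-hit entries are ignored.
#' @param outcomes chronological outcomes, same length.
#' @param t_axis realigned trial axis (e.g. trial index minus the
#'   criterion trial), same length.
#' @param window window span in trials (default 201: `t-100..t+100`).
#' @param step stride of evaluation points along the axis.
#' @return data.frame: `t`, `eh`, `n_post_fa`, `n_post_hit`, `n_hit`.
#' @export
errorHistoryCurve <- function(responses, outcomes, t_axis,
                              window = 201, step = 1) {
  n <- length(outcomes)
  stopifnot(length(responses) == n, length(t_axis) == n)
  half <- ehWindowHalf(window)
  part <- partitionHits(outcomes)
  isFAhit <- seq_len(n) %in% part$hit_post_FA
  isHHhit <- seq_len(n) %in% part$hit_post_hit
  isHit <- outcomes == "hit"
  centers <- seq(1L + half, n - half, by = step)
  rows <- lapply(centers, function(i) {
    w <- (i - half):(i + half)
    fa <- w[isFAhit[w] & !is.na(responses[w])]
    hh <- w[isHHhit[w] & !is.na(responses[w])]
    allh <- w[isHit[w] & !is.na(responses[w])]
    eh <- NA_real_
    if (length(fa) >= 1 && length(hh) >= 1 && length(allh) >= 1) {
      den <- mean(responses[allh])
      if (den != 0) {
        eh <- (mean(responses[fa]) - mean(responses[hh])) / den
      }
    }
    data.frame(t = t_axis[i], eh = eh, n_post_fa = length(fa),
               n_post_hit = length(hh), n_hit = length(allh))
  })
  do.call(rbind, rows)
}

#' Permutation confidence bounds for the error history
#'
#' Within each window, all hit-trial responses are randomly permuted among
#' the hit positions (post-FA, post-hit and other hits keep their trial
#' positions, their responses are exchanged), the error history is
#' recomputed, and the 2.5th/97.5th percentiles over `n_perm` permutations
#' give the 95% confidence interval. The observed value is significant at
#' `t` when it falls outside the interval.
#'
#' @inheritParams errorHistoryCurve
#' @param n_perm permutations per window (default 1000).
#' @param seed RNG seed.
#' @return data.frame: columns of [errorHistoryCurve()] plus `ci_low`,
#'   `ci_high`, `significant`.
#' @export
errorHistoryNull <- function(responses, outcomes, t_axis, window = 201,
                             step = 1, n_perm = 1000, seed = NULL) {
  obs <- errorHistoryCurve(responses, outcomes, t_axis, window, step)
  n <- length(outcomes)
  half <- ehWindowHalf(window)
  part <- partitionHits(outcomes)
  isFAhit <- seq_len(n) %in% part$hit_post_FA
  isHHhit <- seq_len(n) %in% part$hit_post_hit
  isHit <- outcomes == "hit"
  centers <- seq(1L + half, n - half, by = step)
  lo <- rep(NA_real_, length(centers))
  hi <- rep(NA_real_, length(centers))
  withSeed(seed, {
    for (k in seq_along(centers)) {
      i <- centers[k]
      w <- (i - half):(i + half)
      hitw <- w[isHit[w] & !is.na(responses[w])]
      if (length(hitw) < 3) next
      nfa <- sum(isFAhit[w] & !is.na(responses[w]))
      nhh <- sum(isHHhit[w] & !is.na(responses[w]))
      if (nfa < 1 || nhh < 1) next
      rh <- responses[hitw]
      null <- vapply(seq_len(n_perm), function(p) {
        perm <- sample(rh)
        den <- mean(perm)
        if (den == 0) return(NA_real_)
        (mean(perm[seq_len(nfa)]) -
           mean(perm[seq(nfa + 1L, nfa + nhh)])) / den
      }, numeric(1))
      lo[k] <- pctl(null[!is.na(null)], 0.025)
      hi[k] <- pctl(null[!is.na(null)], 0.975)
    }
  })
  obs$ci_low <- lo
  obs$ci_high <- hi
  obs$significant <- !is.na(obs$eh) & !is.na(lo) &
    (obs$eh < lo | obs$eh > hi)
  obs
}

#' Fraction of neurons per class with significant error history
#'
#' @param series named list (per neuron) of data.frames from
#'   [errorHistoryNull()].
#' @param classifications data.frame with `neuron_id` and a class column.
#' @param class_column which column defines the class (default
#'   `learning_class`; use `subclass` for choice/value).
#' @param t_range realigned-axis interval in which significance counts
#'   (default pre-criterion: `c(-Inf, 0)`).
#' @param statistic `"any"` scores a neuron significant when any window in
#'   `t_range` is significant; `"window_fraction"` scores each neuron by
#'   the fraction of its significant windows, which is better calibrated
#'   when many overlapping windows are evaluated.
#' @return data.frame: `class`, `n`, `fraction_significant`.
#' @export
significantFractionByClass <- function(series, classifications,
                                       class_column = "learning_class",
                                       t_range = c(-Inf, 0),
                                       statistic = c("any",
                                                     "window_fraction")) {
  statistic <- match.arg(statistic)
  sig <- vapply(names(series), function(id) {
    d <- series[[id]]
    s <- d$significant[d$t >= t_range[1] & d$t <= t_range[2]]
    if (statistic == "any") as.numeric(any(s, na.rm = TRUE))
    else mean(s, na.rm = TRUE)
  }, numeric(1))
  cls <- classifications[[class_column]][
    match(names(series), classifications$neuron_id)]
  res <- lapply(split(sig, cls), function(s) {
    data.frame(n = length(s), fraction_significant = mean(s))
  })
  out <- do.call(rbind, res)
  data.frame(class = rownames(out), out, row.names = NULL)
}

#' Divergence trial of post-FA vs. post-hit response curves
#'
#' Across subjects, computes rolling-window mean response curves of hit
#' trials preceded by a FA and hit trials preceded by a hit on the
#' criterion-realigned axis, bootstraps 95% bands over subjects (same
#' construction as the behavioural learning onset), and returns the last
#' pre-criterion trial at which the two bands become and remain disjoint.
#'
#' @param per_subject list (one element per subject) of lists with
#'   `responses`, `outcomes`, `t_axis` as in [errorHistoryCurve()].
#' @param window rolling window (trials) for the response means.
#' @param step evaluation stride.
#' @param n_boot,seed bootstrap settings.
#' @return list: `divergence` (realigned trial or `NA`), `t`, `post_fa` and
#'   `post_hit` band data.frames.
#' @export
responseDivergenceTrial <- function(per_subject, window = 201, step = 5,
                                    n_boot = 1000, seed = NULL) {
  stopifnot(length(per_subject) >= 2)
  half <- ehWindowHalf(window)
  curves <- lapply(per_subject, function(s) {
    n <- length(s$outcomes)
    part <- partitionHits(s$outcomes)
    centers <- seq(1L + half, n - half, by = step)
    rows <- lapply(centers, function(i) {
      w <- (i - half):(i + half)
      fa <- intersect(w, part$hit_post_FA)
      hh <- intersect(w, part$hit_post_hit)
      data.frame(
        t = s$t_axis[i],
        post_fa = if (length(fa)) mean(s$responses[fa], na.rm = TRUE)
                  else NA_real_,
        post_hit = if (length(hh)) mean(s$responses[hh], na.rm = TRUE)
                   else NA_real_
      )
    })
    do.call(rbind, rows)
  })
  bands <- bootstrapBands(curves, c("post_fa", "post_hit"), n_boot, seed)
  div <- bandSeparationPoint(
    bands$t,
    list(lo = bands$post_fa$lo, hi = bands$post_fa$hi),
    list(lo = bands$post_hit$lo, hi = bands$post_hit$hi),
    tMax = 0
  )
  list(divergence = div, t = bands$t, post_fa = bands$post_fa,
       post_hit = bands$post_hit)
}

#' Pairwise co-fluctuation of spontaneous activity
#'
#' Pairwise Pearson correlation coefficients between the normalised
#' spontaneous traces of neuron pairs.
#'
#' @param dff neurons x frames matrix of spontaneous normalised traces.
#' @param pairs optional 2-column matrix of neuron indices or ids; default
#'   all unordered pairs.
#' @return data.frame: `neuron_a`, `neuron_b`, `correlation` (`NA` flagged
#'   for zero-variance traces).
#' @export
cofluctuation <- function(dff, pairs = NULL) {
  ids <- rownames(dff) %||% as.character(seq_len(nrow(dff)))
  if (is.null(pairs)) {
    pairs <- t(utils::combn(nrow(dff), 2))
  } else if (is.character(pairs)) {
    pairs <- matrix(match(pairs, ids), ncol = 2)
  }
  sds <- apply(dff, 1, stats::sd)
  cc <- suppressWarnings(stats::cor(t(dff)))
  r <- cc[cbind(pairs[, 1], pairs[, 2])]
  r[sds[pairs[, 1]] == 0 | sds[pairs[, 2]] == 0] <- NA_real_
  data.frame(neuron_a = ids[pairs[, 1]], neuron_b = ids[pairs[, 2]],
             correlation = r)
}

#' Pre/post comparison of pairwise co-fluctuations within a class
#'
#' @param pre,post data.frames from [cofluctuation()] on the pre- and
#'   post-reversal spontaneous segments (matched pairs).
#' @param members neuron ids belonging to the class of interest; only pairs
#'   with both members in the class are compared.
#' @return data.frame of paired differences per retained pair:
#'   `neuron_a`, `neuron_b`, `pre`, `post`, `delta`.
#' @export
comparePhases <- function(pre, post, members) {
  key <- function(d) paste(d$neuron_a, d$neuron_b)
  keep <- pre$neuron_a %in% members & pre$neuron_b %in% members
  m <- match(key(pre)[keep], key(post))
  data.frame(
    neuron_a = pre$neuron_a[keep],
    neuron_b = pre$neuron_b[keep],
    pre = pre$correlation[keep],
    post = post$correlation[m],
    delta = post$correlation[m] - pre$correlation[keep]
  )
}
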
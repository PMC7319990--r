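#' Per-trial response scalars
#'
#' The response of a neuron on a trial is its mean dF/F0 over the 2-s
#' texture-presentation window. Masked neuron-trials propagate as `NA`.
#'
#' @param dff neurons x frames matrix of normalised traces.
#' @param session a [CalciumSession-class].
#' @return neurons x trials matrix of responses (columns named by trial id).
#' @export
trialResponses <- function(dff, session) {
  ft <- frameTrial(session)
  ph <- framePhase(session)
  ids <- trials(session)$trial_id
  resp <- vapply(ids, function(id) {
    idx <- which(ft == id & ph == "texture")
    if (!length(idx)) return(rep(NA_real_, nrow(dff)))
    rowMeans(dff[, idx, drop = FALSE])
  }, numeric(nrow(dff)))
  resp <- matrix(resp, nrow = nrow(dff),
                 dimnames = list(rownames(dff), ids))
  resp
}

#' ROC area under the curve, linear-threshold construction
#'
#' The ROC curve is traced by sweeping `n_thresholds` levels spaced as a
#' linear function from the minimum to the maximum of the pooled responses
#' and plotting, at each level, the fraction of group-`a` trials against
#' the fraction of group-`b` trials whose response strictly exceeds the
#' threshold (ties fall below). Endpoints (0,0) and (1,1) are appended and
#' the area is computed by trapezoidal integration. For continuous data
#' this converges to the pairwise Mann-Whitney AUC as `n_thresholds`
#' grows.
#'
#' @param a,b numeric response vectors for the two trial groups (`NA`s
#'   dropped).
#' @param n_thresholds number of threshold levels (>= 2).
#' @return AUC in `[0, 1]`; degenerate inputs (all pooled responses
#'   identical) return 0.5 with attribute `degenerate = TRUE`.
#' @export
rocAUC <- function(a, b, n_thresholds = 1000) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  stopifnot(length(a) > 0, length(b) > 0, n_thresholds >= 2)
  pool <- c(a, b)
  lo <- min(pool); hi <- max(pool)
  if (hi == lo) {
    return(structure(0.5, degenerate = TRUE))
  }
  th <- seq(lo, hi, length.out = n_thresholds)
  ## bin index of each response: the number of thresholds it strictly
  ## exceeds (ties at a threshold fall below it)
  k <- findInterval(pool, th, left.open = TRUE)
  aucFromBins(k[seq_along(a)], k[-seq_along(a)],
              length(a), length(b), n_thresholds)
}

## AUC of the linear-threshold ROC from per-response exceedance counts:
## fraction exceeding threshold j is the suffix sum of the bin tabulation.
aucFromBins <- function(ka, kb, na, nb, nt) {
  ca <- rev(cumsum(rev(tabulate(ka, nt))))
  cb <- rev(cumsum(rev(tabulate(kb, nt))))
  ## sweep thresholds high -> low: fractions ascend; append (0,0) and (1,1)
  x <- c(0, rev(cb) / nb, 1)
  y <- c(0, rev(ca) / na, 1)
  sum(diff(x) * (y[-length(y)] + y[-1])) / 2
}

#' Discrimination / choice index from two response groups
#'
#' `DI = (AUC - 0.5) x 2`, ranging over `[-1, 1]`. For the discrimination
#' index, group `a` holds P120-texture trials and group `b` P280 trials, so
#' positive values indicate larger responses to P120. For the choice index
#' the groups are lick vs. no-lick trials and positive values indicate
#' lick-preferring responses.
#'
#' @inheritParams rocAUC
#' @return Index value in `[-1, 1]` (attribute `auc` carries the AUC).
#' @export
selectivityIndex <- function(a, b, n_thresholds = 1000) {
  auc <- rocAUC(a, b, n_thresholds)
  structure((as.numeric(auc) - 0.5) * 2, auc = as.numeric(auc),
            degenerate = isTRUE(attr(auc, "degenerate")))
}

#' Permutation test of a selectivity index
#'
#' Builds the sampling distribution of the index by shuffling the group
#' labels of the trials (sampling without replacement) `n_perm` times; the
#' measured index is significant when it falls outside the 2.5th-97.5th
#' percentile interval of that distribution.
#'
#' @param a,b response groups (observed labelling).
#' @param n_perm number of label shuffles (default 10000).
#' @param n_thresholds threshold count for the ROC construction.
#' @param seed RNG seed.
#' @return list: `value`, `auc`, `null_low`, `null_high`, `significant`,
#'   `n_a`, `n_b`, `n_perm`.
#' @export
permutationTest <- function(a, b, n_perm = 10000, n_thresholds = 1000,
                            seed = NULL) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("need at least two trials per label for the permutation test")
  }
  obs <- selectivityIndex(a, b, n_thresholds)
  pool <- c(a, b)
  na <- length(a); nb <- length(b)
  lo0 <- min(pool); hi0 <- max(pool)
  null <- withSeed(seed, {
    if (hi0 == lo0) {
      rep(0, n_perm)
    } else {
      ## thresholds depend only on the pooled responses, which label
      ## shuffles leave unchanged: bin once, re-tabulate per shuffle
      th <- seq(lo0, hi0, length.out = n_thresholds)
      k <- findInterval(pool, th, left.open = TRUE)
      cAll <- rev(cumsum(rev(tabulate(k, n_thresholds))))
      vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(na + nb, na)
        ca <- rev(cumsum(rev(tabulate(k[idx], n_thresholds))))
        x <- c(0, rev(cAll - ca) / nb, 1)
        y <- c(0, rev(ca) / na, 1)
        (sum(diff(x) * (y[-length(y)] + y[-1])) / 2 - 0.5) * 2
      }, numeric(1))
    }
  })
  lo <- pctl(null, 0.025)
  hi <- pctl(null, 0.975)
  list(value = as.numeric(obs), auc = attr(obs, "auc"),
       null_low = lo, null_high = hi,
       significant = as.numeric(obs) < lo || as.numeric(obs) > hi,
       n_a = length(a), n_b = length(b), n_perm = n_perm)
}

#' Selectivity of a set of neurons over a set of trials
#'
#' Computes the discrimination index (`kind = "DI"`, P120 vs. P280 trials)
#' or choice index (`kind = "CI"`, lick vs. no-lick trials) with its
#' permutation significance for every neuron, over a chosen trial subset
#' (e.g. one learning phase, with trials pooled across that phase's
#' sessions).
#'
#' @param responses neurons x trials response matrix from
#'   [trialResponses()].
#' @param trials trial table aligned with the response columns.
#' @param kind `"DI"` or `"CI"`.
#' @param trial_ids subset of trials to use (default: all).
#' @param n_perm,n_thresholds permutation and threshold settings.
#' @param seed master seed; each neuron gets a derived child seed.
#' @param min_per_side windows with fewer trials of either label yield a
#'   flagged missing index.
#' @return data.frame, one row per neuron: `neuron_id`, `index_kind`,
#'   `value`, `auc`, `null_low`, `null_high`, `significant`, `n_a`, `n_b`.
#' @export
computeSelectivity <- function(responses, trials, kind = c("DI", "CI"),
                               trial_ids = trials$trial_id,
                               n_perm = 10000, n_thresholds = 1000,
                               seed = NULL, min_per_side = 5) {
  kind <- match.arg(kind)
  sel <- trials$trial_id %in% trial_ids
  lab <- selectivityLabels(trials, kind)[sel]
  cols <- match(trials$trial_id[sel], as.integer(colnames(responses)))
  resp <- responses[, cols, drop = FALSE]
  seeds <- childSeeds(seed %||% 1L, nrow(resp))
  rows <- lapply(seq_len(nrow(resp)), function(j) {
    a <- resp[j, lab == "a"]
    b <- resp[j, lab == "b"]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < min_per_side || length(b) < min_per_side) {
      return(data.frame(neuron_id = rownames(resp)[j], index_kind = kind,
                        value = NA_real_, auc = NA_real_,
                        null_low = NA_real_, null_high = NA_real_,
                        significant = NA, n_a = length(a), n_b = length(b)))
    }
    pt <- permutationTest(a, b, n_perm, n_thresholds, seed = seeds[j])
    data.frame(neuron_id = rownames(resp)[j], index_kind = kind,
               value = pt$value, auc = pt$auc, null_low = pt$null_low,
               null_high = pt$null_high, significant = pt$significant,
               n_a = pt$n_a, n_b = pt$n_b)
  })
  do.call(rbind, rows)
}

## Group labels for an index kind: "a" is the positive-preference group
## (P120 for DI, lick for CI), "b" the other.
selectivityLabels <- function(trials, kind) {
  if (kind == "DI") {
    ifelse(trials$stimulus == "P120", "a", "b")
  } else {
    ifelse(trials$n_licks_texture > 0, "a", "b")
  }
}

#' Rolling selectivity index across learning
#'
#' Computes DI or CI over a sliding window of trials (default 100 trials
#' every 5), giving the temporal evolution of selectivity across reversal
#' learning. Windows with fewer than `min_per_side` trials of either label
#' are flagged missing. Permutation significance per window is optional
#' (`n_perm = 0` skips it).
#'
#' @inheritParams computeSelectivity
#' @param window,step window length and stride, trials.
#' @return data.frame: one row per neuron x window, with `window_start`,
#'   `window_end`, `window_center` and the selectivity columns.
#' @export
rollingIndex <- function(responses, trials, kind = c("DI", "CI"),
                         window = 100, step = 5, n_perm = 0,
                         n_thresholds = 1000, seed = NULL,
                         min_per_side = 5) {
  kind <- match.arg(kind)
  n <- nrow(trials)
  stopifnot(n >= window)
  starts <- seq(1L, n - window + 1L, by = step)
  lab <- selectivityLabels(trials, kind)
  seeds <- childSeeds(seed %||% 1L, nrow(responses) * length(starts))
  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    w <- seq(starts[k], starts[k] + window - 1L)
    cols <- match(trials$trial_id[w], as.integer(colnames(responses)))
    rows <- lapply(seq_len(nrow(responses)), function(j) {
      a <- responses[j, cols[lab[w] == "a"]]
      b <- responses[j, cols[lab[w] == "b"]]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      base <- data.frame(
        neuron_id = rownames(responses)[j], index_kind = kind,
        window_start = trials$trial_id[w[1]],
        window_end = trials$trial_id[w[window]],
        window_center = trials$trial_id[w[ceiling(window / 2)]],
        value = NA_real_, auc = NA_real_, null_low = NA_real_,
        null_high = NA_real_, significant = NA,
        n_a = length(a), n_b = length(b))
      if (length(a) < min_per_side || length(b) < min_per_side) return(base)
      if (n_perm > 0) {
        pt <- permutationTest(a, b, n_perm, n_thresholds,
                              seed = seeds[(k - 1L) * nrow(responses) + j])
        base$value <- pt$value; base$auc <- pt$auc
        base$null_low <- pt$null_low; base$null_high <- pt$null_high
        base$significant <- pt$significant
      } else {
        v <- selectivityIndex(a, b, n_thresholds)
        base$value <- as.numeric(v); base$auc <- attr(v, "auc")
      }
      base
    })
    out[[k]] <- do.call(rbind, rows)
  }
  do.call(rbind, out)
}

#' Align post-reversal indices to the pre-reversal preference
#'
#' Multiplies post-reversal index values by the sign of the neuron's
#' pre-reversal expert index, so that positive aligned values mean "same
#' preference as before the reversal".
#'
#' @param di_pre pre-reversal index value(s), one per neuron.
#' @param di_post numeric vector or matrix of post-reversal values (rows
#'   matched to `di_pre`).
#' @return Aligned values; neurons with `di_pre == 0` become `NA`.
#' @export
signAlignToPre <- function(di_pre, di_post) {
  s <- sign(di_pre)
  s[s == 0] <- NA
  if (is.matrix(di_post)) di_post * s else di_post * s
}
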
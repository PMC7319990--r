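#' Pre/post stimulus-response categorization (paired t-test)
#'
#' Compares, per neuron and across trials, the average normalised
#' fluorescence over 1 s before versus 1 s after a stimulus onset with a
#' two-sided paired-sample t-test at the 5% significance threshold. The
#' same test run on the control channel audits stimulation-induced
#' artefacts: control-channel positives should stay at the nominal rate.
#'
#' @param pre,post numeric vectors (one entry per trial) of the mean
#'   fluorescence in the 1-s windows before and after stimulus onset.
#' @param alpha significance threshold.
#' @return list: `responsive` (logical), `p_value`, `degenerate` (`TRUE`
#'   when the paired differences have zero variance, in which case the
#'   neuron is flagged not responsive).
#' @export
categorizeStimulusResponse <- function(pre, post, alpha = 0.05) {
  stopifnot(length(pre) == length(post), length(pre) >= 2)
  d <- post - pre
  if (stats::sd(d) == 0) {
    return(list(responsive = FALSE, p_value = NA_real_, degenerate = TRUE))
  }
  p <- stats::t.test(post, pre, paired = TRUE)$p.value
  list(responsive = p < alpha, p_value = p, degenerate = FALSE)
}

#' Learning class from pre- and post-reversal expert selectivity
#'
#' \describe{
#'   \item{non_selective}{significant in neither expert phase}
#'   \item{gained}{significant only post-reversal}
#'   \item{lost}{significant only pre-reversal}
#'   \item{remained}{significant in both with the same sign}
#'   \item{reversed}{significant in both with opposite signs}
#' }
#'
#' @param di_pre,di_post single-neuron rows (lists or 1-row data.frames)
#'   with `value` and `significant` fields, computed on the pre- and
#'   post-reversal expert phases.
#' @return Character scalar, or `NA` (with a `reason` attribute) when an
#'   index is missing.
#' @export
assignLearningClass <- function(di_pre, di_post) {
  if (is.na(di_pre$value) || is.na(di_post$value) ||
      is.na(di_pre$significant) || is.na(di_post$significant)) {
    return(structure(NA_character_, reason = "missing index"))
  }
  sp <- isTRUE(di_pre$significant)
  so <- isTRUE(di_post$significant)
  if (!sp && !so) return("non_selective")
  if (!sp && so) return("gained")
  if (sp && !so) return("lost")
  if (sign(di_pre$value) == sign(di_post$value)) "remained" else "reversed"
}

#' Choice vs. value subdivision of reversed neurons
#'
#' A reversed neuron is a *choice* neuron when its choice index is
#' significant and keeps one sign throughout all three phases (pre-reversal
#' expert, post-reversal naive, post-reversal expert); it is a *value*
#' neuron when the naive-phase CI is not significant or flips sign.
#'
#' @param ci_pre,ci_naive,ci_post single-neuron CI rows with `value` and
#'   `significant` fields.
#' @return `"choice"`, `"value"`, or `NA` (attribute `reason`) when a CI is
#'   not computable.
#' @export
subdivideReversed <- function(ci_pre, ci_naive, ci_post) {
  vals <- c(ci_pre$value, ci_naive$value, ci_post$value)
  sig <- c(ci_pre$significant, ci_naive$significant, ci_post$significant)
  if (anyNA(vals) || anyNA(sig)) {
    return(structure(NA_character_, reason = "CI not computable in a phase"))
  }
  if (all(sig) && length(unique(sign(vals))) == 1) "choice" else "value"
}

#' Classify every neuron across learning phases
#'
#' Computes per-phase DI (pre/post expert, trials pooled across the phase's
#' sessions) and CI (all three phases) for every neuron, assigns the
#' learning class and, for reversed neurons, the choice/value subclass.
#'
#' @param responses neurons x trials matrix from [trialResponses()].
#' @param trials trial table.
#' @param phases phase table from [learningPhases()].
#' @param n_perm,n_thresholds,seed passed to [computeSelectivity()].
#' @param min_per_side minimum trials per label.
#' @return data.frame, one row per neuron: learning_class, subclass, and
#'   per-phase DI/CI values and significance flags.
#' @export
classifyNeurons <- function(responses, trials, phases, n_perm = 10000,
                            n_thresholds = 1000, seed = NULL,
                            min_per_side = 5) {
  seeds <- childSeeds(seed %||% 1L, 5)
  ids <- function(p) trials$trial_id[trials$trial_id %in% phaseTrials(phases, p)]
  diPre <- computeSelectivity(responses, trials, "DI", ids("pre_expert"),
                              n_perm, n_thresholds, seeds[1], min_per_side)
  diPost <- computeSelectivity(responses, trials, "DI", ids("post_expert"),
                               n_perm, n_thresholds, seeds[2], min_per_side)
  ciPre <- computeSelectivity(responses, trials, "CI", ids("pre_expert"),
                              n_perm, n_thresholds, seeds[3], min_per_side)
  ciNaive <- computeSelectivity(responses, trials, "CI", ids("post_naive"),
                                n_perm, n_thresholds, seeds[4], min_per_side)
  ciPost <- computeSelectivity(responses, trials, "CI", ids("post_expert"),
                               n_perm, n_thresholds, seeds[5], min_per_side)
  n <- nrow(responses)
  cls <- character(n); sub <- character(n)
  for (j in seq_len(n)) {
    lc <- assignLearningClass(diPre[j, ], diPost[j, ])
    cls[j] <- lc
    sub[j] <- if (identical(lc, "reversed")) {
      sc <- subdivideReversed(ciPre[j, ], ciNaive[j, ], ciPost[j, ])
      if (is.na(sc)) "unclassifiable" else sc
    } else {
      "none"
    }
  }
  data.frame(
    neuron_id = rownames(responses),
    learning_class = cls,
    subclass = sub,
    di_pre = diPre$value, di_pre_sig = diPre$significant,
    di_post = diPost$value, di_post_sig = diPost$significant,
    ci_pre = ciPre$value, ci_pre_sig = ciPre$significant,
    ci_naive = ciNaive$value, ci_naive_sig = ciNaive$significant,
    ci_post = ciPost$value, ci_post_sig = ciPost$significant,
    row.names = NULL
  )
}

#' Class fractions per subject and pooled
#'
#' @param classifications data.frame from [classifyNeurons()], optionally
#'   with a `subject` column.
#' @return data.frame of fractions per class (and per subject when
#'   available), including the P120-/P280-preferring fractions among
#'   significant neurons per phase.
#' @export
classSummary <- function(classifications) {
  cl <- classifications
  if (!"subject" %in% colnames(cl)) cl$subject <- "pooled"
  lvls <- c("non_selective", "gained", "lost", "remained", "reversed")
  res <- lapply(split(cl, cl$subject), function(d) {
    n <- nrow(d)
    fr <- vapply(lvls, function(x)
      sum(d$learning_class == x, na.rm = TRUE) / n, numeric(1))
    data.frame(
      subject = d$subject[1], n_neurons = n, t(fr),
      frac_P120_pre = sum(d$di_pre_sig & d$di_pre > 0, na.rm = TRUE) / n,
      frac_P280_pre = sum(d$di_pre_sig & d$di_pre < 0, na.rm = TRUE) / n,
      frac_P120_post = sum(d$di_post_sig & d$di_post > 0, na.rm = TRUE) / n,
      frac_P280_post = sum(d$di_post_sig & d$di_post < 0, na.rm = TRUE) / n,
      frac_choice = sum(d$subclass == "choice", na.rm = TRUE) / n,
      frac_value = sum(d$subclass == "value", na.rm = TRUE) / n
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
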
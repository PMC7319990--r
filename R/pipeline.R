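#' Pipeline configuration
#'
#' Stage parameters for [runPipeline()], defaulting to the analysis
#' protocol's values: neuropil coefficient 0.7, 200-trial behavioural
#' windows, 100-trial/5-step selectivity windows, 10,000 DI/CI
#' permutations, 1,000 error-history permutations, 70% expert criterion,
#' and the fixed forest settings of the decoding stage.
#'
#' @param r neuropil coefficient.
#' @param f0_mode dF/F0 baseline dialect.
#' @param behavior_window rolling window for performance curves, trials.
#' @param expert_threshold expert criterion, percent correct.
#' @param selectivity_window,selectivity_step rolling DI/CI windows.
#' @param n_perm_selectivity,n_perm_eh permutation counts.
#' @param eh_window error-history window span (inclusive), trials.
#' @param eh_step evaluation stride of the error-history axis.
#' @param n_thresholds ROC threshold levels.
#' @param min_per_side minimum trials per label for an index.
#' @param decode run the (relatively slow) decoding stage.
#' @param rolling run the rolling-index stage.
#' @param seed master seed for every stochastic stage.
#' @return Named list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(r = 0.7, f0_mode = "trial_baseline_median",
                           behavior_window = 200, expert_threshold = 70,
                           selectivity_window = 100, selectivity_step = 5,
                           n_perm_selectivity = 10000, n_perm_eh = 1000,
                           eh_window = 201, eh_step = 5,
                           n_thresholds = 1000, min_per_side = 5,
                           decode = TRUE, rolling = TRUE, seed = 1) {
  stopifnot(n_perm_selectivity >= 1, n_perm_eh >= 1,
            behavior_window >= 2, selectivity_window >= 2)
  structure(as.list(environment()), class = "pipelineConfig")
}

#' Run the full analysis pipeline on one session
#'
#' Executes preprocess, behaviour, selectivity, classification, decoding
#' and error-history stages on a (typically synthetic) reversal
#' experiment, returning all stage tables plus a JSON-serialisable summary
#' with a provenance block. Two runs with identical input and config are
#' identical in every tabular output.
#'
#' @param session a [CalciumSession-class] covering a full reversal
#'   experiment (with `metadata(session)$reversal_trial`).
#' @param config [pipelineConfig()].
#' @param out_dir optional directory to which stage CSVs and
#'   `summary.json` are written.
#' @return list: `prep_qc`, `behavior` (session performance + curve),
#'   `phases`, `selectivity` (per-phase DI/CI), `classification`,
#'   `decoding` (or `NULL`), `error_history` (per-neuron series),
#'   `summary`.
#' @export
runPipeline <- function(session, config = pipelineConfig(),
                        out_dir = NULL) {
  t0 <- proc.time()[3]
  seeds <- childSeeds(config$seed, 6)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  reversal <- metadata(session)$reversal_trial
  if (is.null(reversal)) stop("session metadata lacks reversal_trial")

  prep <- stage("preprocess", preprocessSession(session, config$r,
                                                config$f0_mode))
  tr <- trials(session)
  perf <- stage("behavior", sessionPerformance(tr))
  curve <- rollingCurve(tr, config$behavior_window)
  phases <- stage("behavior", learningPhases(tr, reversal,
                                             config$behavior_window,
                                             config$expert_threshold))
  resp <- stage("selectivity", trialResponses(prep$dff$dff, session))
  classification <- stage("classification", classifyNeurons(
    resp, tr, phases, config$n_perm_selectivity, config$n_thresholds,
    seed = seeds[1], min_per_side = config$min_per_side))
  rollingDI <- if (config$rolling) {
    stage("selectivity", rollingIndex(resp, tr, "DI",
                                      config$selectivity_window,
                                      config$selectivity_step,
                                      n_perm = 0,
                                      n_thresholds = config$n_thresholds,
                                      seed = seeds[2]))
  } else NULL
  decoding <- if (config$decode) {
    stage("decoding", decodeBehavior(
      session, prep,
      deconv = deconvParams(frame_rate = frameRate(session)),
      seed = seeds[3]))
  } else NULL

  crit <- attr(phases, "criterion_trial")
  tAxis <- realignToCriterion(tr$trial_id, crit)
  eh <- stage("error_history", {
    out <- lapply(seq_len(nrow(resp)), function(j) {
      errorHistoryNull(resp[j, ], tr$outcome, tAxis,
                       window = config$eh_window, step = config$eh_step,
                       n_perm = config$n_perm_eh,
                       seed = seeds[4] + j)
    })
    names(out) <- rownames(resp)
    out
  })
  ehFrac <- significantFractionByClass(eh, classification,
                                       class_column = "learning_class")

  summary <- list(
    provenance = list(
      package_version = as.character(utils::packageVersion("revroc")),
      seed = config$seed,
      config = unclass(config)[vapply(unclass(config), function(x)
        is.numeric(x) || is.character(x) || is.logical(x), logical(1))],
      n_neurons = nrow(session),
      n_trials = nrow(tr)
    ),
    expert_criterion_trial = crit,
    session_performance = perf$performance,
    class_fractions = as.list(table(classification$learning_class)),
    subclass_fractions = as.list(table(classification$subclass)),
    eh_significant_fraction = stats::setNames(
      as.list(ehFrac$fraction_significant), ehFrac$class),
    elapsed_s = round(proc.time()[3] - t0, 2)
  )
  res <- list(prep_qc = prep$qc,
              behavior = list(performance = perf, curve = curve),
              phases = phases, classification = classification,
              rolling_di = rollingDI, decoding = decoding,
              error_history = eh, eh_fractions = ehFrac,
              summary = summary)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(prep$qc, file.path(out_dir, "qc.csv"),
                     row.names = FALSE)
    utils::write.csv(perf, file.path(out_dir, "behavior_sessions.csv"),
                     row.names = FALSE)
    utils::write.csv(classification,
                     file.path(out_dir, "classification.csv"),
                     row.names = FALSE)
    if (!is.null(decoding)) {
      utils::write.csv(decoding, file.path(out_dir, "decoding.csv"),
                       row.names = FALSE)
    }
    ehTab <- do.call(rbind, lapply(names(eh), function(id)
      cbind(neuron_id = id, eh[[id]])))
    utils::write.csv(ehTab, file.path(out_dir, "error_history.csv"),
                     row.names = FALSE)
    summary$elapsed_s <- NULL  # keep the JSON byte-stable across reruns
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}
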
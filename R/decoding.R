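#' Time-lagged predictor design for behavioural decoding
#'
#' Builds, for every usable frame `t`, the predictor vector
#' `[x(t - 500 ms), ..., x(t), ..., x(t + 500 ms)]` as 11 bins of 100 ms of
#' the inferred event-rate trace, centred on zero lag. Bins are defined in
#' time; because 100-ms bins do not tile 11.5-Hz frames evenly, each bin is
#' filled by fractional-overlap weighting of the frames it covers. Lag
#' windows never borrow frames across trial boundaries: contributions from
#' outside the frame's own trial are zero.
#'
#' @param rates numeric vector, inferred event rate per frame.
#' @param behavior numeric vector, behavioural rate per frame (already
#'   downsampled to the imaging frame rate).
#' @param frame_rate imaging rate, Hz.
#' @param frame_trial per-frame trial ids; `NULL` treats the trace as one
#'   trial.
#' @param n_bins,bin_s number and width (s) of the lag bins.
#' @return list of class `LaggedDesign`: `X` (frames x bins matrix), `y`,
#'   `trial` (per-row trial id), `lags_s` (bin centres).
#' @export
buildLaggedDesign <- function(rates, behavior, frame_rate,
                              frame_trial = NULL, n_bins = 11, bin_s = 0.1) {
  n <- length(rates)
  stopifnot(length(behavior) == n)
  maxLag <- (n_bins - 1) / 2 * bin_s
  if (n / frame_rate <= 2 * maxLag) {
    stop("trace shorter than the lag span")
  }
  if (is.null(frame_trial)) frame_trial <- rep(1L, n)
  seg <- segmentIds(frame_trial, n)
  dt <- 1 / frame_rate
  centres <- (seq_len(n_bins) - (n_bins + 1) / 2) * bin_s
  ## constant fractional-overlap weights of frame offsets for each bin:
  ## frame k (relative) covers time [k*dt - dt/2, k*dt + dt/2)
  kmax <- ceiling((maxLag + bin_s / 2) / dt) + 1L
  offs <- seq(-kmax, kmax)
  X <- matrix(0, n, n_bins)
  for (j in seq_len(n_bins)) {
    aj <- centres[j] - bin_s / 2
    bj <- centres[j] + bin_s / 2
    for (k in offs) {
      ov <- min(bj, k * dt + dt / 2) - max(aj, k * dt - dt / 2)
      if (ov <= 0) next
      w <- ov / bin_s
      src <- seq_len(n) + k
      ok <- src >= 1 & src <= n
      ok[ok] <- seg[src[ok]] == seg[ok]
      X[ok, j] <- X[ok, j] + w * rates[src[ok]]
    }
  }
  colnames(X) <- sprintf("lag_%+dms", round(centres * 1000))
  structure(list(X = X, y = behavior, trial = frame_trial,
                 lags_s = centres),
            class = "LaggedDesign")
}

#' Cross-validated random-forest decoding
#'
#' Fits regression forests predicting the behavioural rate from the lagged
#' design, with 5-fold cross-validation over trials (never over frames):
#' each fold trains on 80% of the trials and predicts the held-out trials,
#' so out-of-fold predictions cover every trial. Forest settings follow the
#' decoding protocol: 128 trees, minimum terminal node size 2,
#' `mtry = max(1, floor(p/3))`, impurity variable importance (recorded but
#' unused).
#'
#' @param design a `LaggedDesign`.
#' @param n_trees,min_node forest size and minimum node size.
#' @param mtry predictors sampled per split (`NULL`: `max(1, floor(p/3))`).
#' @param k_folds number of cross-validation folds over trials.
#' @param seed RNG seed (fold assignment and forests).
#' @return list: `predicted` (per frame, out-of-fold), `folds` (per-trial
#'   fold assignment), `importance` (averaged over folds).
#' @export
fitDecoderCV <- function(design, n_trees = 128, min_node = 2, mtry = NULL,
                         k_folds = 5, seed = NULL) {
  X <- design$X
  y <- design$y
  trial <- design$trial
  ut <- unique(trial)
  if (length(ut) < k_folds) stop("need at least k_folds trials")
  p <- ncol(X)
  if (is.null(mtry)) mtry <- max(1, floor(p / 3))
  seeds <- childSeeds(seed %||% 1L, k_folds + 1L)
  foldOf <- withSeed(seeds[k_folds + 1L], {
    sample(rep_len(seq_len(k_folds), length(ut)))
  })
  names(foldOf) <- ut
  pred <- rep(NA_real_, length(y))
  imp <- numeric(p)
  df <- data.frame(y = y, X)
  for (f in seq_len(k_folds)) {
    testTrials <- ut[foldOf == f]
    isTest <- trial %in% testTrials
    fit <- ranger::ranger(
      y ~ ., data = df[!isTest, , drop = FALSE],
      num.trees = n_trees, min.node.size = min_node, mtry = mtry,
      importance = "impurity", seed = seeds[f], num.threads = 1
    )
    pred[isTest] <- stats::predict(fit, df[isTest, , drop = FALSE],
                                   num.threads = 1)$predictions
    imp <- imp + fit$variable.importance / k_folds
  }
  list(predicted = pred, folds = foldOf, importance = imp)
}

#' Prediction power
#'
#' Pearson product-moment correlation between the observed and predicted
#' behavioural rate fluctuations.
#'
#' @param observed,predicted numeric vectors of equal length.
#' @return Correlation coefficient, or `NA` (flagged via attribute
#'   `degenerate`) when either series has zero variance.
#' @export
predictionPower <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  ok <- is.finite(observed) & is.finite(predicted)
  if (stats::sd(observed[ok]) == 0 || stats::sd(predicted[ok]) == 0) {
    return(structure(NA_real_, degenerate = TRUE))
  }
  stats::cor(observed[ok], predicted[ok])
}

#' Control-channel decoding threshold
#'
#' The predictive criterion is five standard deviations above the mean of
#' the prediction powers obtained from the activity-independent control
#' channel across all neurons.
#'
#' @param pp_control numeric vector of control-channel prediction powers
#'   (>= 10 values).
#' @param n_sd number of standard deviations.
#' @return Threshold value.
#' @export
controlThreshold <- function(pp_control, n_sd = 5) {
  pp_control <- pp_control[is.finite(pp_control)]
  if (length(pp_control) < 10) {
    stop("need at least 10 control prediction powers")
  }
  s <- stats::sd(pp_control)
  if (s == 0) stop("degenerate control distribution (zero SD)")
  mean(pp_control) + n_sd * s
}

#' Predictive classification against the control threshold
#'
#' @param pp prediction power(s).
#' @param threshold from [controlThreshold()].
#' @return Logical: `pp > threshold`.
#' @export
classifyPredictive <- function(pp, threshold) {
  pp > threshold
}

#' Decode whisking and licking rates from every neuron
#'
#' Full decoding stage for a session: infers event rates from the
#' activity-channel dF/F0 (trials concatenated), builds the lagged design
#' against each behavioural rate (whisking and licking, computed from the
#' event times with the sliding-window rate estimator and sampled on the
#' frame grid), fits the cross-validated forests, and repeats the identical
#' analysis on the control channel to calibrate the predictive threshold
#' (computed per behaviour).
#'
#' @param session a [CalciumSession-class].
#' @param prep output of [preprocessSession()] for the session.
#' @param behaviors behaviours to decode.
#' @param deconv [deconvParams()].
#' @param seed master seed.
#' @param neurons optional subset of neuron row indices.
#' @return data.frame: one row per neuron x behaviour with `pp`,
#'   `pp_control`, `threshold`, `predictive`.
#' @export
decodeBehavior <- function(session, prep, behaviors = c("whisk", "lick"),
                           deconv = deconvParams(frame_rate =
                                                   frameRate(session)),
                           seed = NULL, neurons = NULL) {
  fr <- frameRate(session)
  ft <- frameTrial(session)
  tr <- trials(session)
  if (is.null(neurons)) neurons <- seq_len(nrow(activity(session)))
  dff <- prep$dff$dff[neurons, , drop = FALSE]
  dffC <- prep$dff_control$dff[neurons, , drop = FALSE]
  dff[!is.finite(dff)] <- 0
  dffC[!is.finite(dffC)] <- 0
  rates <- inferSpikeRates(dff, deconv, ft)$rates
  ratesC <- inferSpikeRates(dffC, deconv, ft)$rates

  ## behavioural rate per frame (sliding 100-ms window, frame-grid samples)
  behTrace <- function(col) {
    out <- numeric(length(ft))
    for (i in seq_len(nrow(tr))) {
      idx <- which(ft == tr$trial_id[i])
      tWithin <- (seq_along(idx) - 0.5) / fr
      out[idx] <- eventRateTrace(tr[[col]][[i]], tWithin)
    }
    out
  }
  beh <- list(whisk = behTrace("whisk_times"), lick = behTrace("lick_times"))

  seeds <- childSeeds(seed %||% 1L, 2L * nrow(rates) * length(behaviors))
  si <- 0L
  out <- list()
  for (b in behaviors) {
    y <- beh[[b]]
    pp <- numeric(nrow(rates)); ppc <- numeric(nrow(rates))
    for (j in seq_len(nrow(rates))) {
      des <- buildLaggedDesign(rates[j, ], y, fr, ft)
      fitA <- fitDecoderCV(des, seed = seeds[si <- si + 1L])
      pp[j] <- predictionPower(y, fitA$predicted)
      desC <- buildLaggedDesign(ratesC[j, ], y, fr, ft)
      fitC <- fitDecoderCV(desC, seed = seeds[si <- si + 1L])
      ppc[j] <- predictionPower(y, fitC$predicted)
    }
    thr <- controlThreshold(ppc)
    out[[b]] <- data.frame(
      neuron_id = rownames(dff),
      behavior = b, pp = pp, pp_control = ppc, threshold = thr,
      predictive = classifyPredictive(pp, thr)
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
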
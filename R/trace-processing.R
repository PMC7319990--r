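#' Neuropil correction
#'
#' Removes out-of-focus neuropil contamination from the measured somatic
#' fluorescence: \eqn{F(t) = F_{measured}(t) - r \times F_{neuropil}(t)}.
#'
#' @param f_measured,f_neuropil numeric matrices (neurons x frames) or
#'   vectors of identical shape.
#' @param r contamination coefficient in `[0, 1]` (default 0.7).
#' @return Corrected fluorescence, same shape as the input.
#' @export
neuropilCorrect <- function(f_measured, f_neuropil, r = 0.7) {
  stopifnot(r >= 0, r <= 1)
  if (!identical(dim(f_measured), dim(f_neuropil)) ||
      length(f_measured) != length(f_neuropil)) {
    stop("f_measured and f_neuropil must share the same shape")
  }
  f_measured - r * f_neuropil
}

#' Per-trial detrending
#'
#' Removes residual slow trends by subtracting the 8th percentile of each
#' trial's trace, each trial independently. Percentiles use linear
#' interpolation between order statistics throughout the package.
#'
#' @param x numeric matrix (neurons x frames) or vector.
#' @param frame_trial per-frame trial ids (`NA` frames form one segment per
#'   contiguous block); `NULL` treats the whole trace as one trial.
#' @param p percentile to subtract (default 0.08).
#' @return Detrended traces, same shape.
#' @export
detrendTrial <- function(x, frame_trial = NULL, p = 0.08) {
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, nrow = 1) else x
  if (ncol(m) == 0) stop("empty trace")
  seg <- segmentIds(frame_trial, ncol(m))
  for (s in unique(seg)) {
    idx <- which(seg == s)
    q <- apply(m[, idx, drop = FALSE], 1, pctl, p = p)
    m[, idx] <- m[, idx, drop = FALSE] - q
  }
  if (vec) as.numeric(m) else m
}

## Frame segmentation: trial ids, with contiguous NA (spontaneous) blocks
## given their own negative segment ids.
segmentIds <- function(frame_trial, n) {
  if (is.null(frame_trial)) return(rep(1L, n))
  stopifnot(length(frame_trial) == n)
  seg <- as.integer(frame_trial)
  if (anyNA(seg)) {
    isna <- is.na(seg)
    blk <- cumsum(isna & !c(FALSE, isna[-n]))
    seg[isna] <- -blk[isna]
  }
  seg
}

#' Normalised calcium traces (dF/F0)
#'
#' Computes \eqn{\Delta F/F_0 = (F - F_0)/F_0} in one of two dialects:
#' \describe{
#'   \item{`trial_baseline_median`}{\eqn{F_0} is, per neuron, the median
#'     across trials of the mean baseline fluorescence over the 1-s
#'     pre-stimulus period of each trial (task sessions).}
#'   \item{`percentile_30`}{\eqn{F_0} is the 30th percentile of each trial's
#'     trace, per neuron and trial (stimulation / spontaneous recordings).}
#' }
#' Neuron-trials whose \eqn{F_0 \le 0} are masked (`NA` in `dff`) rather
#' than producing infinities.
#'
#' @param x corrected (and detrended) fluorescence, neurons x frames.
#' @param frame_trial per-frame trial ids.
#' @param frame_phase per-frame phase labels (needs `"baseline"` frames when
#'   `f0_mode = "trial_baseline_median"`).
#' @param f0_mode baseline dialect, see above.
#' @return list of class `NormalizedTraces`: `dff` (neurons x frames), `f0`
#'   (neurons x trials), `valid` (neurons x trials logical), `f0_mode`,
#'   `trial_ids`.
#' @export
computeDFF <- function(x, frame_trial, frame_phase = NULL,
                       f0_mode = c("trial_baseline_median", "percentile_30")) {
  f0_mode <- match.arg(f0_mode)
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, nrow = 1) else x
  seg <- segmentIds(frame_trial, ncol(m))
  segs <- unique(seg)
  nN <- nrow(m)
  f0 <- matrix(NA_real_, nN, length(segs),
               dimnames = list(rownames(m), NULL))
  if (f0_mode == "trial_baseline_median") {
    if (is.null(frame_phase)) {
      stop("frame_phase is required for the trial_baseline_median dialect")
    }
    baseMeans <- vapply(segs, function(s) {
      idx <- which(seg == s & frame_phase == "baseline")
      if (!length(idx)) return(rep(NA_real_, nN))
      rowMeans(m[, idx, drop = FALSE])
    }, numeric(nN))
    baseMeans <- matrix(baseMeans, nrow = nN)
    f0neuron <- apply(baseMeans, 1, stats::median, na.rm = TRUE)
    f0[] <- f0neuron
  } else {
    for (k in seq_along(segs)) {
      idx <- which(seg == segs[k])
      f0[, k] <- apply(m[, idx, drop = FALSE], 1, pctl, p = 0.30)
    }
  }
  valid <- is.finite(f0) & f0 > 0
  dff <- matrix(NA_real_, nN, ncol(m), dimnames = dimnames(m))
  for (k in seq_along(segs)) {
    idx <- which(seg == segs[k])
    ok <- valid[, k]
    if (any(ok)) {
      dff[ok, idx] <- (m[ok, idx, drop = FALSE] - f0[ok, k]) / f0[ok, k]
    }
  }
  structure(list(dff = if (vec) as.numeric(dff) else dff,
                 f0 = f0, valid = valid, f0_mode = f0_mode,
                 trial_ids = segs),
            class = "NormalizedTraces")
}

#' Savitzky-Golay display smoothing
#'
#' Polynomial-preserving smoothing for display purposes only (2nd order,
#' 500-ms span by default); statistics are never computed on the smoothed
#' trace. Near the trace boundaries the fitting window shrinks so that no
#' data outside the trace is fabricated.
#'
#' @param x numeric vector, or matrix smoothed row-wise.
#' @param frame_rate imaging rate, Hz.
#' @param order polynomial order.
#' @param span_s filter span, seconds (converted to the nearest odd frame
#'   count).
#' @return Smoothed traces, same shape.
#' @export
smoothDisplay <- function(x, frame_rate, order = 2, span_s = 0.5) {
  n <- round(span_s * frame_rate)
  if (n %% 2 == 0) n <- n + 1
  if (n < order + 2) stop("span too small for the requested polynomial order")
  if (!is.null(dim(x))) {
    return(t(apply(x, 1, smoothDisplay, frame_rate = frame_rate,
                   order = order, span_s = span_s)))
  }
  len <- length(x)
  if (len < n) stop("trace shorter than the filter span")
  half <- (n - 1L) %/% 2L
  coef <- signal::sgolay(p = order, n = n)
  centre <- coef[half + 1L, ]
  out <- stats::filter(x, rev(centre), sides = 2)
  out <- as.numeric(out)
  ## shrink the window at the edges: refit the polynomial on the clipped span
  for (i in seq_len(half)) {
    for (side in c("l", "r")) {
      j <- if (side == "l") i else len - i + 1L
      lo <- max(1L, j - half); hi <- min(len, j + half)
      w <- lo:hi
      if (length(w) >= order + 2) {
        fit <- stats::lm.fit(outer(w - j, 0:order, `^`), x[w])
        out[j] <- fit$coefficients[1]
      } else {
        out[j] <- x[j]
      }
    }
  }
  out
}

#' Deconvolution parameters
#'
#' @param ar_decay AR(1) coefficient per frame; `NULL` derives it from
#'   `decay_s` and `frame_rate` as `exp(-1/(decay_s * frame_rate))`.
#' @param decay_s,frame_rate indicator decay time constant and imaging rate
#'   used when `ar_decay` is `NULL`.
#' @param background_mode `"constant"` subtracts the global 8th percentile
#'   before inference; `"variable"` subtracts it per trial.
#' @param saturation_correction apply an indicator-saturation unmixing of
#'   dF/F0 before inference (off by default).
#' @param kd indicator dissociation constant, nM; recorded with the result
#'   and used only by the saturation option's documentation of scale.
#' @param dff_max saturating dF/F0 ceiling used by the saturation option.
#' @return Named list of class `deconvParams`.
#' @export
deconvParams <- function(ar_decay = NULL, decay_s = 1.5, frame_rate = 11.5,
                         background_mode = c("constant", "variable"),
                         saturation_correction = FALSE, kd = 144,
                         dff_max = 5) {
  background_mode <- match.arg(background_mode)
  if (is.null(ar_decay)) ar_decay <- exp(-1 / (decay_s * frame_rate))
  stopifnot(ar_decay > 0, ar_decay < 1)
  structure(list(ar_decay = ar_decay, background_mode = background_mode,
                 saturation_correction = saturation_correction, kd = kd,
                 dff_max = dff_max),
            class = "deconvParams")
}

## Nonnegative AR(1) deconvolution by pool-adjacent-violators (OASIS-style):
## least-squares fit of c with c_t >= gamma * c_(t-1) and c >= 0.
## Returns the denoised trace c; rates are c_t - gamma * c_(t-1).
oasisAR1 <- function(y, gamma) {
  n <- length(y)
  v <- numeric(n); w <- numeric(n); t0 <- integer(n); l <- integer(n)
  k <- 0L
  for (t in seq_len(n)) {
    k <- k + 1L
    v[k] <- y[t]; w[k] <- 1; t0[k] <- t; l[k] <- 1L
    while (k > 1L && v[k] < gamma^l[k - 1L] * v[k - 1L]) {
      gl <- gamma^l[k - 1L]
      wn <- w[k - 1L] + gl^2 * w[k]
      v[k - 1L] <- (w[k - 1L] * v[k - 1L] + gl * w[k] * v[k]) / wn
      w[k - 1L] <- wn
      l[k - 1L] <- l[k - 1L] + l[k]
      k <- k - 1L
    }
  }
  cc <- numeric(n)
  for (i in seq_len(k)) {
    vi <- max(v[i], 0)
    cc[t0[i]:(t0[i] + l[i] - 1L)] <- vi * gamma^(0:(l[i] - 1L))
  }
  cc
}

#' Infer nonnegative event rates from dF/F0
#'
#' Fast nonnegative deconvolution under an AR(1) transient model: after
#' background subtraction, the denoised trace `c` is the least-squares fit
#' of the input subject to `c[t] >= ar_decay * c[t-1]` and `c >= 0`; the
#' inferred rate is the positive innovation `s[t] = c[t] - ar_decay *
#' c[t-1]`. Traces of all trials are concatenated per subject before
#' inference so that across-neuron activity levels remain comparable.
#'
#' @param dff numeric matrix (neurons x frames) or vector of normalised
#'   traces.
#' @param params [deconvParams()].
#' @param frame_trial per-frame trial ids (used by the `"variable"`
#'   background mode).
#' @return list of class `SpikeInference`: `rates` (same shape as input,
#'   `>= 0`), `denoised`, `background`, `residual_sd` per neuron, `params`.
#' @export
inferSpikeRates <- function(dff, params = deconvParams(),
                            frame_trial = NULL) {
  if (!all(is.finite(dff))) stop("non-finite values in input traces")
  vec <- is.null(dim(dff))
  m <- if (vec) matrix(dff, nrow = 1) else dff
  if (params$saturation_correction) {
    ## unmix indicator saturation: free-ligand signal is hyperbolic in
    ## dF/F0 with ceiling dff_max (scale set by kd, which cancels here)
    m <- m / pmax(1 - m / params$dff_max, 0.05)
  }
  g <- params$ar_decay
  bg <- matrix(0, nrow(m), ncol(m))
  if (params$background_mode == "variable" && !is.null(frame_trial)) {
    seg <- segmentIds(frame_trial, ncol(m))
    for (s in unique(seg)) {
      idx <- which(seg == s)
      bg[, idx] <- apply(m[, idx, drop = FALSE], 1, pctl, p = 0.08)
    }
  } else {
    bg[] <- apply(m, 1, pctl, p = 0.08)
  }
  y <- m - bg
  den <- t(vapply(seq_len(nrow(y)), function(j) oasisAR1(y[j, ], g),
                  numeric(ncol(y))))
  rates <- den - g * cbind(0, den[, -ncol(den), drop = FALSE])
  rates <- pmax(rates, 0)
  res <- y - den
  out <- list(rates = if (vec) as.numeric(rates) else rates,
              denoised = if (vec) as.numeric(den) else den,
              background = bg,
              residual_sd = apply(res, 1, stats::sd),
              params = params)
  structure(out, class = "SpikeInference")
}

#' Half-maximum onset time of an averaged response
#'
#' The onset is the first time, within the search window, at which the
#' trial-averaged trace reaches the pre-event baseline plus half of its
#' peak amplitude above baseline. The peak is taken over the search window
#' only (the stimulus-presentation span), avoiding reward-period
#' transients. If the peak does not exceed baseline noise (mean + `k` SD of
#' the pre-event samples) the onset is undefined (`NA`).
#'
#' @param trace trial-averaged aligned trace.
#' @param times time of each sample relative to the alignment event, s.
#' @param search length-2 numeric: search window for peak and crossing, s.
#' @param k baseline-noise multiplier.
#' @return Onset time in seconds, or `NA` if undefined.
#' @export
halfMaxOnset <- function(trace, times, search = c(0, 2), k = 2) {
  stopifnot(length(trace) == length(times))
  base <- trace[times < search[1]]
  b0 <- if (length(base)) mean(base, na.rm = TRUE) else 0
  bsd <- if (length(base) > 1) stats::sd(base, na.rm = TRUE) else 0
  win <- which(times >= search[1] & times <= search[2])
  if (!length(win)) return(NA_real_)
  peak <- max(trace[win], na.rm = TRUE)
  if (!is.finite(peak) || peak <= b0 + k * bsd) return(NA_real_)
  half <- b0 + (peak - b0) / 2
  cross <- win[which(trace[win] >= half)[1]]
  if (is.na(cross)) return(NA_real_)
  times[cross]
}

#' Response onsets aligned to texture onset or first lick
#'
#' For each neuron, averages the dF/F0 trace over the selected (hit) trials
#' aligned either to the texture onset or to the first lick within the
#' texture window, and returns the half-maximum onset time relative to the
#' alignment event.
#'
#' @param dff neurons x frames matrix of normalised traces.
#' @param session a [CalciumSession-class] (frame map and trial table).
#' @param trial_ids trials to include (typically the hit trials of an
#'   expert session).
#' @param align `"texture_onset"` or `"first_lick"`.
#' @param pre_s,post_s window around the alignment event, s.
#' @param search length-2 search window for the peak and crossing, relative
#'   to the event. Defaults to `c(0, post_s)` for texture alignment and
#'   `c(-0.5, post_s)` for lick alignment (stimulus-locked activity rises
#'   before the lick, so lick-aligned onsets may be negative).
#' @return Named numeric vector of onset times (s), `NA` where undefined.
#' @export
responseOnset <- function(dff, session, trial_ids,
                          align = c("texture_onset", "first_lick"),
                          pre_s = 1, post_s = 2, search = NULL) {
  align <- match.arg(align)
  if (is.null(search)) {
    search <- if (align == "texture_onset") c(0, post_s)
              else c(-0.5, post_s)
  }
  if (!length(trial_ids)) stop("no trials to align")
  fr <- frameRate(session)
  tr <- trials(session)
  ft <- frameTrial(session)
  texOn <- metadata(session)$texture_onset_s
  nPre <- round(pre_s * fr); nPost <- round(post_s * fr)
  relTimes <- (seq(-nPre, nPost) + 0.5) / fr
  nN <- nrow(dff)
  acc <- matrix(0, nN, length(relTimes))
  cnt <- matrix(0, nN, length(relTimes))
  for (id in trial_ids) {
    idx <- which(ft == id)
    if (!length(idx)) next
    evT <- if (align == "texture_onset") texOn else {
      rt <- tr$reaction_time_s[tr$trial_id == id]
      if (is.na(rt)) next
      texOn + rt
    }
    evFrame <- idx[1] + floor(evT * fr)
    take <- evFrame + seq(-nPre, nPost)
    ok <- take >= idx[1] & take <= idx[length(idx)]
    vals <- dff[, take[ok], drop = FALSE]
    fin <- is.finite(vals)
    vals[!fin] <- 0
    acc[, ok] <- acc[, ok] + vals
    cnt[, ok] <- cnt[, ok] + fin
  }
  avg <- acc / pmax(cnt, 1)
  avg[cnt == 0] <- NA
  onsets <- vapply(seq_len(nN), function(j) {
    halfMaxOnset(avg[j, ], relTimes, search = search)
  }, numeric(1))
  names(onsets) <- rownames(dff)
  onsets
}

#' Preprocess a session: neuropil correction, detrend, dF/F0
#'
#' Runs the fixed trace-processing order — neuropil correction (activity
#' channel only), per-trial 8th-percentile detrend, then dF/F0 — on both
#' channels of a session. The control channel has no neuropil estimate and
#' skips the correction step.
#'
#' @param session a [CalciumSession-class].
#' @param r neuropil coefficient.
#' @param f0_mode baseline dialect, see [computeDFF()].
#' @return list with `dff` and `dff_control` (`NormalizedTraces`), and `qc`,
#'   a per-neuron data.frame (baseline F0, masked-trial counts).
#' @export
preprocessSession <- function(session, r = 0.7,
                              f0_mode = "trial_baseline_median") {
  ft <- frameTrial(session)
  ph <- framePhase(session)
  np <- neuropilChannel(session)
  f <- if (is.null(np)) activity(session) else
    neuropilCorrect(activity(session), np, r)
  f <- detrendTrial(f, ft)
  nt <- computeDFF(f, ft, ph, f0_mode)
  fc <- detrendTrial(controlChannel(session), ft)
  ntc <- computeDFF(fc, ft, ph, f0_mode)
  qc <- data.frame(
    neuron_id = rownames(activity(session)),
    f0_median = apply(nt$f0, 1, stats::median, na.rm = TRUE),
    n_masked_trials = rowSums(!nt$valid),
    row.names = NULL
  )
  list(dff = nt, dff_control = ntc, qc = qc, r = r)
}
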
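#' CalciumSession: trial-aligned two-channel calcium imaging container
#'
#' `CalciumSession` extends [SummarizedExperiment::SummarizedExperiment] and
#' holds per-neuron fluorescence traces (neurons in rows, imaging frames in
#' columns) for an activity channel (GCaMP6s-like), an activity-independent
#' control channel (mRuby2-like) and, optionally, a local neuropil channel,
#' together with the behavioural trial table and a frame-to-trial map.
#'
#' Assays:
#' \describe{
#'   \item{activity}{measured somatic fluorescence of the activity indicator}
#'   \item{control}{activity-independent fluorophore, used to calibrate
#'     measurement noise}
#'   \item{neuropil}{(optional) local neuropil fluorescence for contamination
#'     correction}
#' }
#'
#' Per-frame annotation lives in `colData`: `trial` (trial id, `NA` for
#' spontaneous segments), `phase` (one of `baseline`, `cue`, `delay`,
#' `texture`, `post`, `spontaneous`) and `time` (seconds from recording
#' start).  The trial table (one row per behavioural trial, see
#' [simulateAgent()] for the schema) is carried in the `trials` slot; for
#' synthetic sessions the per-neuron ground truth is carried in `groundTruth`.
#'
#' @slot trials data.frame, one row per behavioural trial.
#' @slot groundTruth data.frame, one row per neuron (0 rows when unknown).
#'
#' @seealso [simulateExperiment()] to generate synthetic sessions,
#'   [preprocessSession()] for the normalisation pipeline,
#'   [readSession()]/[writeSession()] for on-disk round trips.
#' @export
setClass("CalciumSession",
  contains = "SummarizedExperiment",
  slots = c(trials = "data.frame", groundTruth = "data.frame")
)

setValidity("CalciumSession", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("activity", "control") %in% an)) {
    msg <- c(msg, "assays must include 'activity' and 'control'")
  }
  cd <- colData(object)
  for (col in c("trial", "phase", "time")) {
    if (!col %in% colnames(cd)) {
      msg <- c(msg, sprintf("colData must contain '%s'", col))
    }
  }
  if ("phase" %in% colnames(cd)) {
    ok <- c("baseline", "cue", "delay", "texture", "post", "spontaneous")
    if (!all(cd$phase %in% ok)) {
      msg <- c(msg, "colData$phase contains unknown phase labels")
    }
    if ("trial" %in% colnames(cd) &&
        any(is.na(cd$trial) & cd$phase != "spontaneous")) {
      msg <- c(msg, "every frame must map to a trial or be 'spontaneous'")
    }
  }
  if (nrow(object@trials) > 0L) {
    need <- c("trial_id", "stimulus", "rewarded_stimulus", "outcome")
    miss <- setdiff(need, colnames(object@trials))
    if (length(miss)) {
      msg <- c(msg, sprintf("trials table lacks column(s): %s",
                            paste(miss, collapse = ", ")))
    } else if ("trial" %in% colnames(cd)) {
      tid <- cd$trial[!is.na(cd$trial)]
      if (!all(tid %in% object@trials$trial_id)) {
        msg <- c(msg, "colData$trial refers to trials absent from the trial table")
      }
    }
  }
  fr <- metadata(object)$frame_rate
  if (is.null(fr) || !is.numeric(fr) || fr <= 0) {
    msg <- c(msg, "metadata(x)$frame_rate must be a positive number")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CalciumSession
#'
#' @param activity,control,neuropil numeric matrices, neurons x frames.
#'   `neuropil` may be `NULL`.
#' @param trials data.frame with one row per behavioural trial.
#' @param frameTrial integer vector, trial id of each frame (`NA` for
#'   spontaneous frames).
#' @param framePhase character vector, within-trial phase of each frame.
#' @param frameRate imaging rate in Hz.
#' @param metadata named list of session metadata (subject, session ids, ...).
#' @param groundTruth optional data.frame of per-neuron simulation truth.
#' @return A [CalciumSession-class] object.
#' @export
CalciumSession <- function(activity, control, neuropil = NULL, trials,
                           frameTrial, framePhase, frameRate,
                           metadata = list(), groundTruth = NULL) {
  activity <- as.matrix(activity)
  control <- as.matrix(control)
  assays <- list(activity = activity, control = control)
  if (!is.null(neuropil)) assays$neuropil <- as.matrix(neuropil)
  d <- vapply(assays, dim, integer(2))
  if (any(d[1, ] != d[1, 1]) || any(d[2, ] != d[2, 1])) {
    stop("all trace matrices must share the same neurons x frames shape")
  }
  nf <- ncol(activity)
  if (length(frameTrial) != nf || length(framePhase) != nf) {
    stop("frameTrial/framePhase must have one entry per frame")
  }
  cd <- DataFrame(
    trial = as.integer(frameTrial),
    phase = as.character(framePhase),
    time = (seq_len(nf) - 0.5) / frameRate
  )
  md <- c(list(frame_rate = frameRate, schema_version = SESSION_SCHEMA_VERSION),
          metadata)
  md <- md[!duplicated(names(md))]
  se <- SummarizedExperiment(assays = assays, colData = cd, metadata = md)
  if (is.null(rownames(se))) {
    rownames(se) <- sprintf("neuron_%03d", seq_len(nrow(activity)))
  }
  new("CalciumSession",
      se,
      trials = as.data.frame(trials),
      groundTruth = if (is.null(groundTruth)) data.frame() else
        as.data.frame(groundTruth))
}

SESSION_SCHEMA_VERSION <- "1.0"

#' @describeIn CalciumSession-class activity-channel trace matrix
#' @param x a `CalciumSession`
#' @export
setMethod("activity", "CalciumSession", function(x) assay(x, "activity"))

#' @describeIn CalciumSession-class control-channel trace matrix
#' @export
setMethod("controlChannel", "CalciumSession", function(x) assay(x, "control"))

#' @describeIn CalciumSession-class neuropil trace matrix (or NULL)
#' @export
setMethod("neuropilChannel", "CalciumSession", function(x) {
  if ("neuropil" %in% SummarizedExperiment::assayNames(x)) {
    assay(x, "neuropil")
  } else {
    NULL
  }
})

#' @describeIn CalciumSession-class behavioural trial table
#' @export
setMethod("trials", "CalciumSession", function(x) x@trials)

#' @describeIn CalciumSession-class replace the trial table
#' @param value replacement value
#' @export
setMethod("trials<-", "CalciumSession", function(x, value) {
  x@trials <- as.data.frame(value)
  validObject(x)
  x
})

#' @describeIn CalciumSession-class imaging frame rate, Hz
#' @export
setMethod("frameRate", "CalciumSession",
          function(x) metadata(x)$frame_rate)

#' @describeIn CalciumSession-class per-frame trial id (NA = spontaneous)
#' @export
setMethod("frameTrial", "CalciumSession", function(x) colData(x)$trial)

#' @describeIn CalciumSession-class per-frame within-trial phase label
#' @export
setMethod("framePhase", "CalciumSession", function(x) colData(x)$phase)

#' @describeIn CalciumSession-class per-frame time from recording start, s
#' @export
setMethod("frameTime", "CalciumSession", function(x) colData(x)$time)

#' @describeIn CalciumSession-class per-neuron simulation ground truth
#' @export
setMethod("groundTruth", "CalciumSession", function(x) x@groundTruth)

setMethod("show", "CalciumSession", function(object) {
  cat(sprintf("CalciumSession: %d neurons x %d frames @ %.1f Hz\n",
              nrow(object), ncol(object), frameRate(object)))
  tr <- trials(object)
  if (nrow(tr)) {
    ns <- length(unique(tr$session_id))
    cat(sprintf("  %d trials in %d session(s); outcomes: %s\n",
                nrow(tr), ns,
                paste(sprintf("%s=%d", names(table(tr$outcome)),
                              as.integer(table(tr$outcome))),
                      collapse = " ")))
  }
  if (nrow(object@groundTruth)) {
    cat(sprintf("  ground truth: %s\n",
                paste(sprintf("%s=%d",
                              names(table(object@groundTruth$true_class)),
                              as.integer(table(object@groundTruth$true_class))),
                      collapse = " ")))
  }
  invisible(NULL)
})
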
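#' Write a session to disk
#'
#' Serialises a [CalciumSession-class] to a plain-text directory: a
#' `metadata.json` (frame rate, schema version, free-form metadata), a
#' `trials.csv` with event-time list-columns encoded as `;`-separated
#' strings, a `frames.csv` frame-to-trial map, one CSV per trace channel,
#' and `ground_truth.csv` when present. The round trip through
#' [readSession()] is lossless up to numeric text precision.
#'
#' @param session a [CalciumSession-class].
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
writeSession <- function(session, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  md <- metadata(session)
  md$n_neurons <- nrow(session)
  md$n_frames <- ncol(session)
  jsonlite::write_json(md, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  tr <- trials(session)
  for (col in c("lick_times", "whisk_times")) {
    if (col %in% colnames(tr)) {
      tr[[col]] <- vapply(tr[[col]], function(x)
        paste(format(x, digits = 10, trim = TRUE, scientific = FALSE),
              collapse = ";"), character(1))
      tr[[col]][tr[[col]] == ""] <- NA_character_
    }
  }
  utils::write.csv(tr, file.path(path, "trials.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(trial = frameTrial(session), phase = framePhase(session)),
    file.path(path, "frames.csv"), row.names = FALSE)
  writeMat <- function(m, file) {
    utils::write.csv(data.frame(neuron_id = rownames(m), m,
                                check.names = FALSE),
                     file.path(path, file), row.names = FALSE)
  }
  writeMat(activity(session), "traces_activity.csv")
  writeMat(controlChannel(session), "traces_control.csv")
  np <- neuropilChannel(session)
  if (!is.null(np)) writeMat(np, "traces_neuropil.csv")
  gt <- groundTruth(session)
  if (nrow(gt)) {
    utils::write.csv(gt, file.path(path, "ground_truth.csv"),
                     row.names = FALSE)
  }
  invisible(path)
}

#' Read a session from disk
#'
#' Inverse of [writeSession()]; validates the schema version and the shape
#' consistency of all datasets, failing with a message naming the
#' offending dataset.
#'
#' @param path session directory.
#' @return A [CalciumSession-class].
#' @export
readSession <- function(path) {
  need <- function(file) {
    fp <- file.path(path, file)
    if (!file.exists(fp)) stop("missing dataset: ", file)
    fp
  }
  md <- jsonlite::read_json(need("metadata.json"), simplifyVector = TRUE)
  if (!identical(as.character(md$schema_version), SESSION_SCHEMA_VERSION)) {
    stop("unknown schema version: ",
         md$schema_version %||% "<absent>", " (expected ",
         SESSION_SCHEMA_VERSION, ")")
  }
  tr <- utils::read.csv(need("trials.csv"), stringsAsFactors = FALSE)
  for (col in c("lick_times", "whisk_times")) {
    if (col %in% colnames(tr)) {
      tr[[col]] <- I(lapply(tr[[col]], function(x) {
        if (is.na(x) || x == "") numeric(0)
        else as.numeric(strsplit(x, ";", fixed = TRUE)[[1]])
      }))
    }
  }
  fm <- utils::read.csv(need("frames.csv"), stringsAsFactors = FALSE)
  readMat <- function(file) {
    d <- utils::read.csv(need(file), check.names = FALSE,
                         stringsAsFactors = FALSE)
    m <- as.matrix(d[, -1, drop = FALSE])
    dimnames(m) <- list(d[[1]], NULL)
    if (ncol(m) != nrow(fm)) {
      stop("dataset ", file, " has ", ncol(m),
           " frames but frames.csv describes ", nrow(fm))
    }
    m
  }
  act <- readMat("traces_activity.csv")
  ctrl <- readMat("traces_control.csv")
  if (nrow(ctrl) != nrow(act)) {
    stop("dataset traces_control.csv has a different neuron count")
  }
  np <- if (file.exists(file.path(path, "traces_neuropil.csv"))) {
    readMat("traces_neuropil.csv")
  } else NULL
  gt <- if (file.exists(file.path(path, "ground_truth.csv"))) {
    utils::read.csv(file.path(path, "ground_truth.csv"),
                    stringsAsFactors = FALSE)
  } else NULL
  keep <- setdiff(names(md), c("frame_rate", "schema_version",
                               "n_neurons", "n_frames"))
  CalciumSession(
    activity = act, control = ctrl, neuropil = np, trials = tr,
    frameTrial = fm$trial, framePhase = fm$phase,
    frameRate = md$frame_rate, metadata = md[keep], groundTruth = gt)
}
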
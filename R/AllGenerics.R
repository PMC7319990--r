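#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#' @importFrom S4Vectors DataFrame metadata
#' @export metadata
#' @export assay
#' @export colData
NULL

#' @export
setGeneric("activity", function(x, ...) standardGeneric("activity"))

#' @export
setGeneric("controlChannel", function(x, ...) standardGeneric("controlChannel"))

#' @export
setGeneric("neuropilChannel", function(x, ...) standardGeneric("neuropilChannel"))

#' @export
setGeneric("trials", function(x, ...) standardGeneric("trials"))

#' @export
setGeneric("trials<-", function(x, value) standardGeneric("trials<-"))

#' @export
setGeneric("frameRate", function(x, ...) standardGeneric("frameRate"))

#' @export
setGeneric("frameTrial", function(x, ...) standardGeneric("frameTrial"))

#' @export
setGeneric("framePhase", function(x, ...) standardGeneric("framePhase"))

#' @export
setGeneric("frameTime", function(x, ...) standardGeneric("frameTime"))

#' @export
setGeneric("groundTruth", function(x, ...) standardGeneric("groundTruth"))
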
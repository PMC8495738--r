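#' @include AllClasses.R
NULL

#' @export
setGeneric("times", function(x) standardGeneric("times"))
#' @export
setGeneric("signalValues", function(x) standardGeneric("signalValues"))
#' @export
setGeneric("strainId", function(x) standardGeneric("strainId"))
#' @export
setGeneric("runId", function(x) standardGeneric("runId"))
#' @export
setGeneric("reporterId", function(x) standardGeneric("reporterId"))
#' @export
setGeneric("genotypeClass", function(x) standardGeneric("genotypeClass"))
#' @export
setGeneric("processingLog", function(x) standardGeneric("processingLog"))
#' @export
setGeneric("period", function(x) standardGeneric("period"))
#' @export
setGeneric("rae", function(x) standardGeneric("rae"))
#' @export
setGeneric("rhythmLabel", function(x) standardGeneric("rhythmLabel"))
#' @export
setGeneric("amplitude", function(x) standardGeneric("amplitude"))
#' @export
setGeneric("components", function(x) standardGeneric("components"))
#' @export
setGeneric("intervalBounds", function(x) standardGeneric("intervalBounds"))
#' @export
setGeneric("finalCandidates", function(x) standardGeneric("finalCandidates"))
#' @export
setGeneric("primaryHits", function(x) standardGeneric("primaryHits"))
#' @export
setGeneric("strainSummaries", function(x) standardGeneric("strainSummaries"))
#' @export
setGeneric("accounting", function(x) standardGeneric("accounting"))

#' @export
setGeneric("trimWindow",
  function(x, head_h = 12, tail_h = 12) standardGeneric("trimWindow"))
#' @export
setGeneric("detrendTrace",
  function(x, method = c("linear", "polynomial"), order = 1L)
    standardGeneric("detrendTrace"))
#' @export
setGeneric("normalizeToMean", function(x, epsilon = 1e-6)
  standardGeneric("normalizeToMean"))
#' @export
setGeneric("estimatePeriod",
  function(x, circadian_window = c(16, 32), rae_threshold = 0.5,
           max_components = 4L, damping = FALSE)
    standardGeneric("estimatePeriod"))
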
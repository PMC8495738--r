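#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a LuminescenceTrace
#'
#' @param run_id,plate_id,well,strain_id,reporter_id single strings
#'   identifying the well.
#' @param genotype_class one of \code{"WT"}, \code{"KO"}, \code{"parental"}.
#' @param times numeric vector of sampling times, hours since DD transfer,
#'   strictly increasing.
#' @param values numeric vector of signal values, same length as
#'   \code{times}.
#' @param processing_log list of transforms already applied (normally empty).
#' @return a [LuminescenceTrace-class] object.
#' @examples
#' tr <- luminescenceTrace(times = 0:47,
#'                         values = 100 + 50 * cos(2 * pi * (0:47) / 22))
#' tr
#' @export
luminescenceTrace <- function(times, values, run_id = "run1",
                              plate_id = "plate1", well = "A01",
                              strain_id = "WT", genotype_class = "WT",
                              reporter_id = "reporter",
                              processing_log = list()) {
  new("LuminescenceTrace", runId = as.character(run_id),
      plateId = as.character(plate_id), well = as.character(well),
      strainId = as.character(strain_id),
      genotypeClass = as.character(genotype_class),
      reporterId = as.character(reporter_id),
      times = as.numeric(times), values = as.numeric(values),
      processingLog = processing_log)
}

#' Construct a TraceSet from a list of traces
#'
#' @param traces list of [LuminescenceTrace-class] objects.
#' @return a [TraceSet-class].
#' @export
traceSet <- function(traces = list()) new("TraceSet", traces = traces)

#' @describeIn luminescenceTrace sampling times (hours) of a trace.
#' @param x a trace.
#' @export
setMethod("times", "LuminescenceTrace", function(x) x@times)

#' @describeIn luminescenceTrace signal values of a trace.
#' @export
setMethod("signalValues", "LuminescenceTrace", function(x) x@values)

#' @describeIn luminescenceTrace strain identifier.
#' @export
setMethod("strainId", "LuminescenceTrace", function(x) x@strainId)

#' @describeIn luminescenceTrace run identifier.
#' @export
setMethod("runId", "LuminescenceTrace", function(x) x@runId)

#' @describeIn luminescenceTrace reporter identifier.
#' @export
setMethod("reporterId", "LuminescenceTrace", function(x) x@reporterId)

#' @describeIn luminescenceTrace genotype class.
#' @export
setMethod("genotypeClass", "LuminescenceTrace", function(x) x@genotypeClass)

#' @describeIn luminescenceTrace list of transforms applied so far.
#' @export
setMethod("processingLog", "LuminescenceTrace", function(x) x@processingLog)

setMethod("show", "LuminescenceTrace", function(object) {
  cat(sprintf(
    "LuminescenceTrace: %s [%s] run=%s plate=%s well=%s reporter=%s\n",
    object@strainId, object@genotypeClass, object@runId, object@plateId,
    object@well, object@reporterId))
  cat(sprintf("  %d samples, t = %.2f..%.2f h, signal mean %.3g\n",
              length(object@times), min(object@times), max(object@times),
              mean(object@values)))
  if (length(object@processingLog))
    cat("  processing:",
        paste(vapply(object@processingLog, `[[`, "", "name"),
              collapse = " -> "), "\n")
})

#' @export
setMethod("length", "TraceSet", function(x) length(x@traces))

#' @export
setMethod("[[", "TraceSet", function(x, i) x@traces[[i]])

#' @export
setMethod("[", "TraceSet", function(x, i, j, ..., drop = TRUE)
  traceSet(x@traces[i]))

#' @export
setMethod("names", "TraceSet", function(x)
  vapply(x@traces, function(tr)
    paste(tr@runId, tr@plateId, tr@well, sep = "/"), character(1)))

setMethod("show", "TraceSet", function(object) {
  cat(sprintf("TraceSet with %d traces\n", length(object)))
  if (length(object)) {
    runs <- unique(vapply(object@traces, runId, character(1)))
    strains <- unique(vapply(object@traces, strainId, character(1)))
    cat(sprintf("  %d run(s), %d strain(s)\n", length(runs),
                length(strains)))
  }
})

#' Convert a TraceSet to the long-format trace table
#'
#' One row per (well, timepoint), columns \code{run_id, plate_id, well,
#' strain_id, genotype_class, reporter_id, time_h, signal}.
#'
#' @param x a [TraceSet-class].
#' @param row.names,optional,... ignored, present for generic compatibility.
#' @return a data.frame.
#' @export
as.data.frame.TraceSet <- function(x, row.names = NULL, optional = FALSE,
                                   ...) {
  if (!length(x@traces))
    return(data.frame(run_id = character(), plate_id = character(),
                      well = character(), strain_id = character(),
                      genotype_class = character(),
                      reporter_id = character(), time_h = numeric(),
                      signal = numeric()))
  do.call(rbind, lapply(x@traces, function(tr)
    data.frame(run_id = tr@runId, plate_id = tr@plateId, well = tr@well,
               strain_id = tr@strainId, genotype_class = tr@genotypeClass,
               reporter_id = tr@reporterId, time_h = tr@times,
               signal = tr@values)))
}

setMethod("as.data.frame", "TraceSet", as.data.frame.TraceSet)

#' @describeIn estimatePeriod estimated period (hours) of an estimate.
#' @export
setMethod("period", "PeriodEstimate", function(x) x@period)

#' @describeIn estimatePeriod relative amplitude error of an estimate.
#' @export
setMethod("rae", "PeriodEstimate", function(x) x@rae)

#' @describeIn estimatePeriod rhythmicity label of an estimate.
#' @export
setMethod("rhythmLabel", "PeriodEstimate", function(x) x@rhythmLabel)

#' @describeIn estimatePeriod amplitude of the reported component.
#' @export
setMethod("amplitude", "PeriodEstimate", function(x) x@amplitude)

setMethod("show", "PeriodEstimate", function(object) {
  cat(sprintf("PeriodEstimate: %s (%s, %s)\n", object@strainId,
              object@genotypeClass, object@reporterId))
  if (is.na(object@period)) {
    cat(sprintf("  %s (no circadian period)\n", object@rhythmLabel))
  } else {
    cat(sprintf("  tau = %.2f +/- %.2f h, amplitude %.3g, RAE %.3f [%s]\n",
                object@period, object@periodSe, object@amplitude,
                object@rae, object@rhythmLabel))
  }
})

#' @describeIn fitCosineModel component table (amplitude-descending).
#' @export
setMethod("components", "DampedCosineModel", function(x) x@components)

setMethod("show", "DampedCosineModel", function(object) {
  cat(sprintf(
    "DampedCosineModel: %d component(s), n = %d, SSE = %.4g%s\n",
    nrow(object@components), object@nObs, object@sse,
    if (object@converged) "" else " (NOT converged)"))
  if (nrow(object@components)) {
    cmp <- object@components
    for (i in seq_len(nrow(cmp)))
      cat(sprintf("  A=%.3g tau=%.3f h phi=%.2f h lambda=%.3g/h\n",
                  cmp$amplitude[i], cmp$period[i], cmp$phase[i],
                  cmp$damping[i]))
  }
})

#' @describeIn wtToleranceInterval lower/upper bounds of the interval.
#' @export
setMethod("intervalBounds", "ToleranceInterval", function(x)
  c(lower = x@lower, upper = x@upper))

setMethod("show", "ToleranceInterval", function(object) {
  cat(sprintf(
    "ToleranceInterval: %.3f +/- %d*%.4f h -> [%.3f, %.3f] (n_wt = %d)\n",
    object@mean, as.integer(object@k), object@sd, object@lower,
    object@upper, object@nWt))
  if (!is.na(object@shapiroP))
    cat(sprintf("  Shapiro-Wilk W = %.4f, p = %.3g%s\n", object@shapiroW,
                object@shapiroP,
                if (object@shapiroP < 0.05) " (normality questionable)"
                else ""))
})

setMethod("show", "ScreenAccounting", function(object) {
  cat("ScreenAccounting:\n")
  cat(sprintf("  listed %d, unavailable %d -> crossed %d\n",
              object@nListed, object@nUnavailable, object@nCrossed))
  cat(sprintf("  failed %d, re-crossed %d, rescued %d -> analyzed %d\n",
              object@nFailedInitial, object@nRecrossAttempted,
              object@nRescued, object@nAnalyzed))
  if (object@nArrhythmicExcluded > 0)
    cat(sprintf("  arrhythmic excluded: %d\n", object@nArrhythmicExcluded))
})

#' @describeIn runScreen final candidate strain ids.
#' @export
setMethod("finalCandidates", "ScreenResult", function(x) x@finalCandidates)

#' @describeIn runScreen primary hit table.
#' @export
setMethod("primaryHits", "ScreenResult", function(x) x@primaryHits)

#' @describeIn runScreen per-strain x reporter summary table.
#' @export
setMethod("strainSummaries", "ScreenResult", function(x) x@summaries)

#' @describeIn runScreen screen accounting block (or NULL).
#' @export
setMethod("accounting", "ScreenResult", function(x) x@accounting)

setMethod("show", "ScreenResult", function(object) {
  cat("ScreenResult\n")
  cat(sprintf("  %d period estimates, %d delta-tau replicates\n",
              nrow(object@estimates), nrow(object@deltas)))
  cat(sprintf("  WT tolerance interval: [%.3f, %.3f] h\n",
              object@primaryInterval@lower, object@primaryInterval@upper))
  cat(sprintf("  primary hits: %d; final candidates: %d\n",
              nrow(object@primaryHits), length(object@finalCandidates)))
})
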
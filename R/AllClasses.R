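#' @import methods
NULL

setClassUnion("ToleranceIntervalOrNULL", "NULL")
setClassUnion("ScreenAccountingOrNULL", "NULL")
setClassUnion("DampedCosineModelOrNULL", "NULL")

#' LuminescenceTrace: one well's bioluminescence time course
#'
#' Container for a single well's luciferase signal recorded by CCD camera
#' imaging of a 96-well plate, annotated with its run, plate, well position,
#' strain and reporter. Times are hours since the transfer to constant
#' darkness (DD); timestamps are explicit and may be irregular. Every
#' preprocessing transform applied to the trace is appended to
#' \code{processingLog} as a named list (transform name plus parameters), so
#' an analysed trace carries its own provenance.
#'
#' @slot runId character, CCD camera run identifier.
#' @slot plateId character, plate identifier within the run.
#' @slot well character, well position (e.g. "A01").
#' @slot strainId character, strain identifier.
#' @slot genotypeClass character, one of \code{"WT"}, \code{"KO"},
#'   \code{"parental"}.
#' @slot reporterId character, luciferase reporter identifier (e.g. a
#'   core-clock promoter reporter or a clock-output fusion).
#' @slot times numeric, strictly increasing sampling times in hours.
#' @slot values numeric, signal values, same length as \code{times}.
#' @slot processingLog list of applied transforms (name + parameters).
#'
#' @seealso [luminescenceTrace()], [trimWindow()], [detrendTrace()],
#'   [normalizeToMean()]
#' @exportClass LuminescenceTrace
setClass("LuminescenceTrace",
  representation(
    runId = "character", plateId = "character", well = "character",
    strainId = "character", genotypeClass = "character",
    reporterId = "character", times = "numeric", values = "numeric",
    processingLog = "list"
  ),
  prototype(
    runId = "run1", plateId = "plate1", well = "A01",
    strainId = "WT", genotypeClass = "WT", reporterId = "reporter",
    times = c(0, 1), values = c(0, 0), processingLog = list()
  )
)

setValidity("LuminescenceTrace", function(object) {
  msg <- character()
  for (s in c("runId", "plateId", "well", "strainId", "genotypeClass",
              "reporterId")) {
    if (length(slot(object, s)) != 1L || is.na(slot(object, s)))
      msg <- c(msg, sprintf("'%s' must be a single non-NA string", s))
  }
  if (!(object@genotypeClass %in% c("WT", "KO", "parental")))
    msg <- c(msg, "genotypeClass must be one of 'WT', 'KO', 'parental'")
  if (length(object@times) != length(object@values))
    msg <- c(msg, "times and values must have equal length")
  if (length(object@times) < 2L)
    msg <- c(msg, "a trace needs at least 2 samples")
  if (length(object@times) >= 2L && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "all signal values must be finite")
  if (length(msg)) msg else TRUE
})

#' TraceSet: a collection of luminescence traces
#'
#' Ordered collection of [LuminescenceTrace-class] objects, typically one per
#' analysed well across one or more CCD camera runs. Supports \code{length},
#' \code{[}, \code{[[} and conversion to the long-format trace table via
#' \code{as.data.frame}.
#'
#' @slot traces list of [LuminescenceTrace-class] objects.
#'
#' @seealso [traceSet()], [readTraces()], [simulateRun()]
#' @exportClass TraceSet
setClass("TraceSet", representation(traces = "list"),
  prototype(traces = list()))

setValidity("TraceSet", function(object) {
  ok <- vapply(object@traces, is, logical(1), class2 = "LuminescenceTrace")
  if (all(ok)) TRUE else
    sprintf("elements %s are not LuminescenceTrace objects",
            paste(which(!ok), collapse = ", "))
})

#' DampedCosineModel: fitted multi-component cosine model
#'
#' Result of nonlinear least-squares fitting of
#' \deqn{y(t) = c + b t + \sum_k A_k e^{-\lambda_k t}
#'   \cos\{2\pi (t - \phi_k)/\tau_k\}}
#' to a (detrended) trace, as produced by [fitCosineModel()]. Components are
#' stored amplitude-descending in a data frame with columns
#' \code{amplitude}, \code{period}, \code{phase}, \code{damping},
#' \code{amplitude_se}, \code{period_se}. Amplitudes are non-negative by
#' convention (sign absorbed into phase); phases lie in \code{[0, period)}.
#'
#' @slot intercept numeric, baseline intercept \eqn{c} (signal units).
#' @slot slope numeric, residual linear trend \eqn{b} (signal units/hour).
#' @slot components data.frame of cosine components, amplitude-descending.
#' @slot sse numeric, residual sum of squares of the fit.
#' @slot nObs integer, number of observations fitted.
#' @slot converged logical, optimizer convergence status.
#'
#' @exportClass DampedCosineModel
setClass("DampedCosineModel",
  representation(
    intercept = "numeric", slope = "numeric", components = "data.frame",
    sse = "numeric", nObs = "integer", converged = "logical"
  ),
  prototype(intercept = 0, slope = 0,
            components = data.frame(amplitude = numeric(),
                                    period = numeric(), phase = numeric(),
                                    damping = numeric(),
                                    amplitude_se = numeric(),
                                    period_se = numeric()),
            sse = 0, nObs = 0L, converged = TRUE)
)

setValidity("DampedCosineModel", function(object) {
  msg <- character()
  cmp <- object@components
  need <- c("amplitude", "period", "phase", "damping",
            "amplitude_se", "period_se")
  if (!all(need %in% names(cmp)))
    msg <- c(msg, paste("components must have columns:",
                        paste(need, collapse = ", ")))
  else {
    if (any(cmp$amplitude < 0)) msg <- c(msg, "amplitudes must be >= 0")
    if (any(cmp$period <= 0)) msg <- c(msg, "periods must be > 0")
    if (any(cmp$damping < 0)) msg <- c(msg, "damping rates must be >= 0")
    if (is.unsorted(rev(cmp$amplitude)))
      msg <- c(msg, "components must be sorted by amplitude, descending")
  }
  if (length(object@sse) != 1L || object@sse < 0)
    msg <- c(msg, "sse must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' PeriodEstimate: per-trace period and rhythmicity call
#'
#' Summary of FFT-NLLS analysis of one trace, as produced by
#' [estimatePeriod()]: the circadian period \eqn{\tau} (the largest-amplitude
#' fitted component whose period lies in the circadian search window), its
#' standard error, amplitude, relative amplitude error (RAE: half-width of
#' the ~95\% amplitude confidence interval divided by the amplitude), and the
#' rhythmicity label. \code{period} is \code{NA} for traces labelled
#' arrhythmic. \code{rawMean} carries the raw-signal mean of the trace before
#' detrending, used for low-signal classification against plate WT levels;
#' \code{normalized} records whether the estimate came from a
#' mean-normalized rescue of a low-signal trace.
#'
#' @slot period numeric, estimated period in hours (NA if arrhythmic).
#' @slot periodSe numeric, standard error of the period (hours).
#' @slot amplitude numeric, amplitude of the reported component.
#' @slot rae numeric, relative amplitude error (dimensionless, >= 0).
#' @slot rhythmLabel character, one of \code{"rhythmic"}, \code{"arrhythmic"},
#'   \code{"low_signal"}.
#' @slot circadianWindow numeric(2), period search window in hours.
#' @slot fit the underlying [DampedCosineModel-class], or NULL if no model
#'   could be fitted.
#' @slot runId,plateId,well,strainId,genotypeClass,reporterId trace metadata.
#' @slot rawMean numeric, mean raw signal of the analysed window.
#' @slot normalized logical, TRUE if period came from the normalized trace.
#'
#' @exportClass PeriodEstimate
setClass("PeriodEstimate",
  representation(
    period = "numeric", periodSe = "numeric", amplitude = "numeric",
    rae = "numeric", rhythmLabel = "character",
    circadianWindow = "numeric", fit = "ANY",
    runId = "character", plateId = "character", well = "character",
    strainId = "character", genotypeClass = "character",
    reporterId = "character", rawMean = "numeric", normalized = "logical"
  ),
  prototype(period = NA_real_, periodSe = NA_real_, amplitude = NA_real_,
            rae = NA_real_, rhythmLabel = "arrhythmic",
            circadianWindow = c(16, 32), fit = NULL,
            runId = NA_character_, plateId = NA_character_,
            well = NA_character_, strainId = NA_character_,
            genotypeClass = "KO", reporterId = NA_character_,
            rawMean = NA_real_, normalized = FALSE)
)

setValidity("PeriodEstimate", function(object) {
  msg <- character()
  if (!(object@rhythmLabel %in% c("rhythmic", "arrhythmic", "low_signal")))
    msg <- c(msg, "rhythmLabel must be rhythmic, arrhythmic or low_signal")
  if (length(object@circadianWindow) != 2L ||
      object@circadianWindow[1] >= object@circadianWindow[2])
    msg <- c(msg, "circadianWindow must be (lo, hi) with lo < hi")
  if (!is.na(object@rae) && object@rae < 0)
    msg <- c(msg, "rae must be >= 0")
  if (object@rhythmLabel %in% c("rhythmic", "low_signal") &&
      is.na(object@period))
    msg <- c(msg, "rhythmic/low_signal estimates must carry a period")
  if (!is.null(object@fit) && !is(object@fit, "DampedCosineModel"))
    msg <- c(msg, "fit must be a DampedCosineModel or NULL")
  if (length(msg)) msg else TRUE
})

#' ToleranceInterval: wild-type delta-tau tolerance interval
#'
#' The screen's hit-calling threshold: mean of the wild-type \eqn{\Delta\tau}
#' population plus/minus \code{k} sample standard deviations (default
#' \code{k = 3}, covering ~99.7\% of a normal WT population). The
#' Shapiro-Wilk normality statistic of the WT sample is computed and stored;
#' see [wtToleranceInterval()].
#'
#' @slot mean numeric, WT delta-tau mean (hours).
#' @slot sd numeric, WT delta-tau sample standard deviation (hours).
#' @slot k numeric, SD multiplier.
#' @slot lower,upper numeric, interval bounds mean -/+ k*sd.
#' @slot shapiroW,shapiroP numeric, Shapiro-Wilk statistic and p-value.
#' @slot nWt integer, number of WT delta-tau values used.
#'
#' @exportClass ToleranceInterval
setClass("ToleranceInterval",
  representation(mean = "numeric", sd = "numeric", k = "numeric",
                 lower = "numeric", upper = "numeric",
                 shapiroW = "numeric", shapiroP = "numeric",
                 nWt = "integer"),
  prototype(mean = 0, sd = 0, k = 3, lower = 0, upper = 0,
            shapiroW = NA_real_, shapiroP = NA_real_, nWt = 0L)
)

setValidity("ToleranceInterval", function(object) {
  msg <- character()
  if (object@k <= 0) msg <- c(msg, "k must be > 0")
  if (object@sd < 0) msg <- c(msg, "sd must be >= 0")
  if (object@sd > 0 && object@lower >= object@upper)
    msg <- c(msg, "lower must be < upper when sd > 0")
  if (abs(object@lower - (object@mean - object@k * object@sd)) > 1e-8 ||
      abs(object@upper - (object@mean + object@k * object@sd)) > 1e-8)
    msg <- c(msg, "bounds must equal mean -/+ k*sd")
  if (length(msg)) msg else TRUE
})

#' ScreenAccounting: bookkeeping of a reverse-genetic screen
#'
#' Derived accounting of how a knockout catalogue funnels down to the set of
#' strains actually analysed: of \code{nListed} catalogued loci,
#' \code{nUnavailable} had no knockout available, leaving
#' \code{nCrossed = nListed - nUnavailable} crosses; \code{nFailedInitial}
#' of those yielded no usable progeny, \code{nRecrossAttempted} were
#' re-crossed with an alternative reporter location and \code{nRescued}
#' thereby recovered, so
#' \code{nAnalyzed = nCrossed - nFailedInitial + nRescued}.
#'
#' @slot nListed,nUnavailable,nCrossed,nFailedInitial integer counts.
#' @slot nRecrossAttempted,nRescued,nAnalyzed,nArrhythmicExcluded integer
#'   counts.
#'
#' @seealso [screenAccounting()]
#' @exportClass ScreenAccounting
setClass("ScreenAccounting",
  representation(nListed = "integer", nUnavailable = "integer",
                 nCrossed = "integer", nFailedInitial = "integer",
                 nRecrossAttempted = "integer", nRescued = "integer",
                 nAnalyzed = "integer", nArrhythmicExcluded = "integer"),
  prototype(nListed = 0L, nUnavailable = 0L, nCrossed = 0L,
            nFailedInitial = 0L, nRecrossAttempted = 0L, nRescued = 0L,
            nAnalyzed = 0L, nArrhythmicExcluded = 0L)
)

setValidity("ScreenAccounting", function(object) {
  msg <- character()
  cnt <- c(object@nListed, object@nUnavailable, object@nCrossed,
           object@nFailedInitial, object@nRecrossAttempted,
           object@nRescued, object@nAnalyzed, object@nArrhythmicExcluded)
  if (any(is.na(cnt)) || any(cnt < 0L))
    msg <- c(msg, "all counts must be non-negative")
  if (object@nUnavailable > object@nListed)
    msg <- c(msg, "nUnavailable cannot exceed nListed")
  if (object@nCrossed != object@nListed - object@nUnavailable)
    msg <- c(msg, "nCrossed must equal nListed - nUnavailable")
  if (object@nRescued > object@nRecrossAttempted)
    msg <- c(msg, "nRescued cannot exceed nRecrossAttempted")
  if (object@nRecrossAttempted > object@nFailedInitial)
    msg <- c(msg, "nRecrossAttempted cannot exceed nFailedInitial")
  if (object@nAnalyzed !=
      object@nCrossed - object@nFailedInitial + object@nRescued)
    msg <- c(msg, "nAnalyzed must equal nCrossed - nFailedInitial + nRescued")
  if (length(msg)) msg else TRUE
})

setIs("ToleranceInterval", "ToleranceIntervalOrNULL")
setIs("ScreenAccounting", "ScreenAccountingOrNULL")
setIs("DampedCosineModel", "DampedCosineModelOrNULL")

#' ScreenResult: full outcome of a dual-reporter circadian screen
#'
#' Bundle of everything the screening stage produces: per-replicate
#' delta-tau tables, per-strain summaries under each reporter, the WT
#' tolerance intervals, the primary hit list, dual-reporter concordance
#' calls, and the final candidate list (strains whose medians fall outside
#' the tolerance interval under both reporters with the same sign of
#' deviation). Produced by [runScreen()].
#'
#' @slot estimates data.frame of per-trace period estimates.
#' @slot deltas data.frame of per-replicate delta-tau values.
#' @slot summaries data.frame of per-strain x reporter summaries with
#'   classification.
#' @slot primaryInterval,secondaryInterval WT [ToleranceInterval-class]s
#'   (secondary NULL when the screen had a single reporter).
#' @slot primaryHits data.frame, strains outside the primary interval.
#' @slot concordance data.frame of per-strain reporter concordance labels
#'   and Welch t-test p-values.
#' @slot finalCandidates character, strain ids confirmed under both
#'   reporters.
#' @slot accounting [ScreenAccounting-class] or NULL.
#'
#' @exportClass ScreenResult
setClass("ScreenResult",
  representation(
    estimates = "data.frame", deltas = "data.frame",
    summaries = "data.frame",
    primaryInterval = "ToleranceInterval",
    secondaryInterval = "ToleranceIntervalOrNULL",
    primaryHits = "data.frame", concordance = "data.frame",
    finalCandidates = "character",
    accounting = "ScreenAccountingOrNULL"
  ),
  prototype(estimates = data.frame(), deltas = data.frame(),
            summaries = data.frame(),
            primaryInterval = new("ToleranceInterval"),
            secondaryInterval = NULL, primaryHits = data.frame(),
            concordance = data.frame(), finalCandidates = character(),
            accounting = NULL)
)

setValidity("ScreenResult", function(object) {
  msg <- character()
  if (length(object@finalCandidates) &&
      nrow(object@primaryHits) &&
      !all(object@finalCandidates %in% object@primaryHits$strain_id))
    msg <- c(msg, "finalCandidates must be a subset of primaryHits strains")
  if (length(msg)) msg else TRUE
})
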
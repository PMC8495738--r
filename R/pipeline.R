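#' @include AllClasses.R accessors.R preprocess.R rhythm.R screening.R
NULL

#' Analysis pipeline configuration
#'
#' Collects every tunable of the standard pipeline with its default. The
#' defaults encode the screen's published analysis settings where stated
#' (12 h trimmed from each end, 3-SD tolerance interval, alpha = 0.05) and
#' conventional FFT-NLLS settings otherwise (RAE threshold 0.5, circadian
#' window 16-32 h, up to 4 components).
#'
#' @param trim_head_h,trim_tail_h hours discarded from each end of every
#'   trace before analysis.
#' @param detrend_method,detrend_order trend removal settings (see
#'   [detrendTrace()]).
#' @param circadian_window numeric(2), period search window in hours.
#' @param rae_threshold maximum relative amplitude error for a rhythmic
#'   call.
#' @param low_signal_fraction raw-mean cutoff (fraction of plate WT median)
#'   below which a non-rhythmic trace is retried after mean normalization.
#' @param max_components maximum FFT-NLLS cosine components.
#' @param damping fit per-component damping (default off).
#' @param interval_k SD multiplier of the WT tolerance interval.
#' @param alpha significance level of the reporter-concordance t-test.
#' @param min_replicates minimum replicates per strain; below it a strain
#'   is \code{insufficient_n}.
#' @param rhythm_floor minimum fraction of replicates with a recovered
#'   period; below it a strain is classified arrhythmic.
#' @return a list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(trim_head_h = 12, trim_tail_h = 12,
                           detrend_method = "linear", detrend_order = 1L,
                           circadian_window = c(16, 32),
                           rae_threshold = 0.5, low_signal_fraction = 0.1,
                           max_components = 4L, damping = FALSE,
                           interval_k = 3, alpha = 0.05,
                           min_replicates = 3L, rhythm_floor = 0.5) {
  if (trim_head_h < 0 || trim_tail_h < 0) stop("trim hours must be >= 0")
  if (circadian_window[1] >= circadian_window[2])
    stop("circadian_window must be (lo, hi) with lo < hi")
  for (nm in c("rae_threshold", "low_signal_fraction", "interval_k",
               "alpha", "rhythm_floor"))
    if (get(nm) <= 0) stop(nm, " must be positive")
  structure(as.list(environment())[setdiff(ls(), "nm")],
            class = "PipelineConfig")
}

#' Estimate periods for every trace of a set
#'
#' Applies the standard preprocessing (trim, detrend) and FFT-NLLS period
#' estimation to every well, then performs the low-signal rescue: traces
#' that came out arrhythmic but whose raw mean signal is below
#' \code{low_signal_fraction} of their run's wild-type median raw mean are
#' re-analysed after mean normalization (on the raw scale); if the
#' normalized trace is rhythmic, the well is labelled \code{low_signal} and
#' keeps the recovered period.
#'
#' @param traces a [TraceSet-class] of raw traces.
#' @param config a [pipelineConfig()].
#' @return data.frame with one row per trace: \code{run_id, plate_id,
#'   well, strain_id, genotype_class, reporter_id, period, period_se,
#'   amplitude, rae, rhythm_label, raw_mean, normalized}.
#' @export
analyzeTraces <- function(traces, config = pipelineConfig()) {
  stopifnot(is(traces, "TraceSet"))
  cfg <- config
  n <- length(traces)
  analyse_one <- function(tr) {
    trimmed <- trimWindow(tr, cfg$trim_head_h, cfg$trim_tail_h)
    detr <- detrendTrace(trimmed, cfg$detrend_method, cfg$detrend_order)
    est <- estimatePeriod(detr, cfg$circadian_window, cfg$rae_threshold,
                          cfg$max_components, cfg$damping)
    list(trimmed = trimmed, est = est, raw_mean = mean(trimmed@values))
  }
  res <- lapply(traces@traces, analyse_one)
  df <- do.call(rbind, lapply(res, function(r) {
    e <- r$est
    data.frame(run_id = e@runId, plate_id = e@plateId, well = e@well,
               strain_id = e@strainId, genotype_class = e@genotypeClass,
               reporter_id = e@reporterId, period = e@period,
               period_se = e@periodSe, amplitude = e@amplitude,
               rae = e@rae, rhythm_label = e@rhythmLabel,
               raw_mean = r$raw_mean, normalized = FALSE)
  }))

  # wells whose raw mean falls below the low-signal floor (fraction of the
  # run's WT median raw signal) are "apparently arrhythmic" at raw scale:
  # their call comes from the mean-normalized re-analysis instead, and a
  # rhythmic normalized trace is labelled low_signal with period reported
  runkey <- paste(df$reporter_id, df$run_id)
  for (key in unique(runkey)) {
    in_run <- runkey == key
    wt_mean <- stats::median(df$raw_mean[in_run &
                                           df$genotype_class == "WT"])
    if (!is.finite(wt_mean)) next
    retry <- which(in_run &
                     df$raw_mean < cfg$low_signal_fraction * wt_mean)
    for (i in retry) {
      norm <- tryCatch(normalizeToMean(res[[i]]$trimmed),
                       error = function(e) NULL)
      est <- if (is.null(norm)) NULL else
        estimatePeriod(detrendTrace(norm, cfg$detrend_method,
                                    cfg$detrend_order),
                       cfg$circadian_window, cfg$rae_threshold,
                       cfg$max_components, cfg$damping)
      if (!is.null(est) && est@rhythmLabel == "rhythmic") {
        df$period[i] <- est@period
        df$period_se[i] <- est@periodSe
        df$amplitude[i] <- est@amplitude
        df$rae[i] <- est@rae
        df$rhythm_label[i] <- "low_signal"
        df$normalized[i] <- TRUE
      } else {
        df$period[i] <- NA_real_
        df$period_se[i] <- NA_real_
        df$rhythm_label[i] <- "arrhythmic"
      }
    }
  }
  rownames(df) <- NULL
  df
}

## per-strain x reporter summaries (KO strains only)
.summarize_all <- function(deltas, estimates, min_n) {
  ko_est <- estimates[estimates$genotype_class != "WT", , drop = FALSE]
  keys <- unique(ko_est[, c("strain_id", "reporter_id")])
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sid <- keys$strain_id[i]; rep_id <- keys$reporter_id[i]
    est_sel <- ko_est$strain_id == sid & ko_est$reporter_id == rep_id
    d_sel <- deltas$strain_id == sid & deltas$reporter_id == rep_id
    n_rep <- sum(est_sel)
    summarizeStrain(
      deltas$delta_tau[d_sel], strain_id = sid, reporter_id = rep_id,
      min_n = min_n,
      rhythm_fraction = sum(!is.na(ko_est$period[est_sel])) / n_rep,
      low_signal_fraction =
        sum(ko_est$rhythm_label[est_sel] == "low_signal") / n_rep)
  }))
  rownames(out) <- NULL
  out[order(out$strain_id), , drop = FALSE]
}

.screen_one_reporter <- function(traces, cfg) {
  est <- analyzeTraces(traces, cfg)
  refs <- runWTReference(est)
  deltas <- computeDeltaTau(est, refs)
  wt_d <- deltas$delta_tau[deltas$genotype_class %in% c("WT", "parental")]
  interval <- wtToleranceInterval(wt_d, k = cfg$interval_k)
  summaries <- .summarize_all(deltas, est, cfg$min_replicates)
  summaries <- callPrimaryHits(summaries, interval, cfg$rhythm_floor)
  list(estimates = est, deltas = deltas, interval = interval,
       summaries = summaries)
}

#' Run the full dual-reporter screen pipeline
#'
#' End-to-end analysis: per-trace preprocessing and FFT-NLLS period
#' estimation, per-run WT references, per-replicate delta-tau, WT
#' tolerance interval, strain medians and hit classification under the
#' primary reporter; then, when a secondary (output-reporter) dataset is
#' supplied, the same under the secondary reporter, Welch concordance
#' t-tests, and the final-candidate intersection (median outside the
#' interval under both reporters, same sign). Without a secondary dataset
#' all primary hits are reported \code{pending}.
#'
#' @param primary [TraceSet-class] of the primary (core-clock reporter)
#'   screen.
#' @param secondary optional [TraceSet-class] of the secondary
#'   (output-reporter) screen.
#' @param config a [pipelineConfig()].
#' @param accounting optional [ScreenAccounting-class] describing the
#'   strain catalogue funnel.
#' @return a [ScreenResult-class].
#' @export
runScreen <- function(primary, secondary = NULL,
                      config = pipelineConfig(), accounting = NULL) {
  cfg <- config
  p <- .screen_one_reporter(primary, cfg)
  summaries <- p$summaries
  deltas <- p$deltas
  estimates <- p$estimates
  sec_interval <- NULL
  concordance <- data.frame(strain_id = character(), label = character(),
                            p_value = numeric())
  if (!is.null(secondary) && length(secondary)) {
    s <- .screen_one_reporter(secondary, cfg)
    sec_interval <- s$interval
    summaries <- rbind(summaries, s$summaries)
    deltas <- rbind(deltas, s$deltas)
    estimates <- rbind(estimates, s$estimates)
    strains <- unique(p$summaries$strain_id)
    concordance <- do.call(rbind, lapply(strains, function(sid) {
      pd <- p$deltas$delta_tau[p$deltas$strain_id == sid]
      sd_ <- s$deltas$delta_tau[s$deltas$strain_id == sid]
      cc <- reporterConcordance(pd, sd_, alpha = cfg$alpha)
      data.frame(strain_id = sid, label = cc$label, p_value = cc$p_value)
    }))
    final <- finalizeCandidates(p$summaries, s$summaries, concordance)
  } else {
    final <- finalizeCandidates(
      p$summaries,
      data.frame(strain_id = character(), classification = character()),
      NULL)
  }
  hits <- attr(p$summaries, "hits")
  new("ScreenResult", estimates = estimates, deltas = deltas,
      summaries = summaries, primaryInterval = p$interval,
      secondaryInterval = sec_interval,
      primaryHits = if (is.null(hits)) data.frame() else hits,
      concordance = final,
      finalCandidates = final$strain_id[final$status == "final"],
      accounting = accounting)
}
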
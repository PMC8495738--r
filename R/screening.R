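#' @include AllClasses.R accessors.R
NULL

#' Per-run wild-type reference periods
#'
#' Every strain's period is compared with the internal WT controls of its
#' own camera run, absorbing run-to-run technical variation. The reference
#' is the arithmetic mean of the rhythmic WT replicate periods in the run.
#'
#' @param estimates per-trace estimate table as returned by
#'   [analyzeTraces()] (needs columns \code{run_id}, \code{reporter_id},
#'   \code{genotype_class}, \code{period}, \code{rhythm_label}).
#' @return data.frame with one row per (reporter_id, run_id):
#'   \code{wt_reference} (hours) and \code{n_wt}. Runs without any rhythmic
#'   WT replicate are dropped with a warning (delta-tau is undefined for
#'   their wells).
#' @export
runWTReference <- function(estimates) {
  if (!nrow(estimates)) stop("no estimates supplied")
  runs <- unique(estimates[, c("reporter_id", "run_id")])
  refs <- lapply(seq_len(nrow(runs)), function(i) {
    sel <- estimates$reporter_id == runs$reporter_id[i] &
      estimates$run_id == runs$run_id[i] &
      estimates$genotype_class == "WT" &
      estimates$rhythm_label == "rhythmic" & !is.na(estimates$period)
    data.frame(reporter_id = runs$reporter_id[i], run_id = runs$run_id[i],
               wt_reference = if (any(sel)) mean(estimates$period[sel])
                              else NA_real_,
               n_wt = sum(sel))
  })
  out <- do.call(rbind, refs)
  if (!any(out$n_wt > 0))
    stop("no run contains a rhythmic WT control; cannot form references")
  bad <- out$n_wt == 0
  if (any(bad))
    warning(sprintf(
      "excluding %d run(s) without rhythmic WT controls: %s", sum(bad),
      paste(out$run_id[bad], collapse = ", ")))
  out[!bad, , drop = FALSE]
}

#' Per-replicate period changes against run WT references
#'
#' Computes delta-tau = replicate period minus the WT reference of the
#' replicate's own run, for every replicate with a recovered period
#' (rhythmic, or low-signal rescued by normalization). Arrhythmic
#' replicates and replicates from runs without a WT reference are skipped
#' and counted in the \code{"skipped"} attribute.
#'
#' @param estimates per-trace estimate table (see [analyzeTraces()]).
#' @param wt_refs reference table from [runWTReference()].
#' @return data.frame with columns \code{strain_id}, \code{run_id},
#'   \code{reporter_id}, \code{genotype_class}, \code{well},
#'   \code{rhythm_label}, \code{delta_tau}; attribute \code{skipped} holds
#'   the counts of skipped replicates.
#' @export
computeDeltaTau <- function(estimates, wt_refs) {
  key <- paste(estimates$reporter_id, estimates$run_id)
  refkey <- paste(wt_refs$reporter_id, wt_refs$run_id)
  ref <- wt_refs$wt_reference[match(key, refkey)]
  usable <- !is.na(estimates$period) &
    estimates$rhythm_label %in% c("rhythmic", "low_signal") & !is.na(ref)
  skipped <- c(arrhythmic = sum(estimates$rhythm_label == "arrhythmic"),
               no_reference = sum(is.na(ref) &
                 estimates$rhythm_label != "arrhythmic"))
  out <- data.frame(strain_id = estimates$strain_id[usable],
                    run_id = estimates$run_id[usable],
                    reporter_id = estimates$reporter_id[usable],
                    genotype_class = estimates$genotype_class[usable],
                    well = estimates$well[usable],
                    rhythm_label = estimates$rhythm_label[usable],
                    delta_tau = estimates$period[usable] - ref[usable])
  attr(out, "skipped") <- skipped
  out
}

#' Wild-type delta-tau tolerance interval
#'
#' Builds the screen's hit-calling interval from the delta-tau values of
#' individual WT wells: mean plus/minus \code{k} sample standard deviations
#' (default \code{k = 3}, covering ~99.7\% of a normal WT population). The
#' normality of the WT sample is checked by Shapiro-Wilk; a p-value below
#' 0.05 (normality rejected) triggers a warning but never blocks interval
#' construction.
#'
#' @param wt_deltas numeric vector of WT delta-tau values (hours), n >= 3.
#' @param k SD multiplier.
#' @return a [ToleranceInterval-class].
#' @examples
#' wtToleranceInterval(c(-0.2, -0.1, 0, 0.1, 0.2))
#' @export
wtToleranceInterval <- function(wt_deltas, k = 3) {
  wt_deltas <- wt_deltas[!is.na(wt_deltas)]
  n <- length(wt_deltas)
  if (n < 3L) stop("at least 3 WT delta-tau values are required")
  mu <- mean(wt_deltas)
  sigma <- stats::sd(wt_deltas)
  if (sigma == 0) warning("all WT delta-tau values equal: zero-width interval")
  sw <- if (sigma > 0 && n <= 5000) stats::shapiro.test(wt_deltas)
        else NULL
  sw_w <- if (is.null(sw)) NA_real_ else unname(sw$statistic)
  sw_p <- if (is.null(sw)) NA_real_ else sw$p.value
  if (!is.na(sw_p) && sw_p < 0.05)
    warning(sprintf(
      "Shapiro-Wilk rejects normality of the WT population (p = %.3g)",
      sw_p))
  new("ToleranceInterval", mean = mu, sd = sigma, k = k,
      lower = mu - k * sigma, upper = mu + k * sigma,
      shapiroW = sw_w, shapiroP = sw_p, nWt = n)
}

#' Summarise one strain's delta-tau replicates
#'
#' Medians are used instead of means to damp the effect of outlier
#' replicates. Strains with fewer than \code{min_n} replicates are marked
#' \code{insufficient_n} (screens require enough progeny per cross).
#'
#' @param deltas numeric vector of delta-tau replicate values for one
#'   strain under one reporter.
#' @param strain_id,reporter_id identifiers carried into the summary.
#' @param min_n minimum replicate count.
#' @param rhythm_fraction fraction of the strain's replicates with a
#'   recovered period (supplied by the pipeline; NA when unknown).
#' @param low_signal_fraction fraction of replicates whose period came from
#'   normalization rescue.
#' @return one-row data.frame: \code{strain_id, reporter_id,
#'   median_delta_tau, iqr, n_replicates, rhythm_fraction,
#'   low_signal_fraction, classification} (classification is
#'   \code{"insufficient_n"} or \code{"unclassified"}; hit classes are set
#'   by [callPrimaryHits()]).
#' @export
summarizeStrain <- function(deltas, strain_id = "strain",
                            reporter_id = "reporter", min_n = 3L,
                            rhythm_fraction = NA_real_,
                            low_signal_fraction = 0) {
  deltas <- deltas[!is.na(deltas)]
  n <- length(deltas)
  data.frame(strain_id = strain_id, reporter_id = reporter_id,
             median_delta_tau = if (n) stats::median(deltas) else NA_real_,
             iqr = if (n) stats::IQR(deltas) else NA_real_,
             n_replicates = n, rhythm_fraction = rhythm_fraction,
             low_signal_fraction = low_signal_fraction,
             classification = if (n < min_n) "insufficient_n"
                              else "unclassified")
}

#' Classify strain medians against the WT tolerance interval
#'
#' Strains whose median delta-tau falls strictly below the lower bound are
#' \code{short} hits, strictly above the upper bound \code{long} hits
#' (medians exactly on a bound are \code{within_interval}: "outside the
#' interval" is read as strict exceedance). Strains whose fraction of
#' rhythmic replicates is below \code{rhythm_floor} are classified
#' \code{arrhythmic} and are never hits; strains dominated by
#' normalization-rescued replicates that are not hits are reported
#' \code{low_signal}.
#'
#' @param summaries strain summary table ([summarizeStrain()] rows).
#' @param interval a [ToleranceInterval-class].
#' @param rhythm_floor minimum fraction of replicates with a recovered
#'   period for a strain to be classifiable.
#' @return the summary table with \code{classification} filled in;
#'   attribute \code{hits} holds the subset classified short or long.
#' @export
callPrimaryHits <- function(summaries, interval, rhythm_floor = 0.5) {
  stopifnot(is(interval, "ToleranceInterval"))
  cls <- summaries$classification
  for (i in seq_len(nrow(summaries))) {
    rf <- summaries$rhythm_fraction[i]
    if (!is.na(rf) && rf < rhythm_floor) { cls[i] <- "arrhythmic"; next }
    if (cls[i] == "insufficient_n") next
    med <- summaries$median_delta_tau[i]
    if (is.na(med)) { cls[i] <- "arrhythmic"; next }
    cls[i] <- if (med < interval@lower) "short"
              else if (med > interval@upper) "long"
              else if (summaries$low_signal_fraction[i] > 0.5) "low_signal"
              else "within_interval"
  }
  summaries$classification <- cls
  attr(summaries, "hits") <-
    summaries[cls %in% c("short", "long"), , drop = FALSE]
  summaries
}

#' Dual-reporter concordance of a strain's period change
#'
#' Welch two-sample t-test between a strain's delta-tau replicates under
#' the primary (core-clock) and secondary (output) reporters. A significant
#' difference (p below \code{alpha}) labels the strain discordant; fewer
#' than 2 replicates under either reporter leaves it untested.
#'
#' @param primary_deltas,secondary_deltas numeric vectors of delta-tau
#'   replicates.
#' @param alpha significance level.
#' @return list with \code{label} ("concordant", "discordant" or
#'   "untested") and \code{p_value}.
#' @export
reporterConcordance <- function(primary_deltas, secondary_deltas,
                                alpha = 0.05) {
  primary_deltas <- primary_deltas[!is.na(primary_deltas)]
  secondary_deltas <- secondary_deltas[!is.na(secondary_deltas)]
  if (length(primary_deltas) < 2L || length(secondary_deltas) < 2L)
    return(list(label = "untested", p_value = NA_real_))
  if (stats::sd(primary_deltas) == 0 && stats::sd(secondary_deltas) == 0) {
    same <- isTRUE(all.equal(mean(primary_deltas), mean(secondary_deltas)))
    return(list(label = if (same) "concordant" else "discordant",
                p_value = if (same) 1 else 0))
  }
  p <- stats::t.test(primary_deltas, secondary_deltas,
                     var.equal = FALSE)$p.value
  list(label = if (p < alpha) "discordant" else "concordant", p_value = p)
}

#' Intersect primary hits with the secondary (output-reporter) screen
#'
#' The conservative confirmation rule: a strain is a final candidate if and
#' only if its median delta-tau lies outside the tolerance interval under
#' BOTH reporters with the same sign of deviation. Primary hits without
#' usable secondary data are reported \code{pending}, never candidates. The
#' Welch concordance label is attached as annotation: a strain may be
#' discordant by t-test yet final if both medians are shifted the same way.
#'
#' @param primary_summaries classified summary table of the primary screen
#'   (after [callPrimaryHits()]).
#' @param secondary_summaries classified summary table of the secondary
#'   screen against its own tolerance interval.
#' @param concordance data.frame with columns \code{strain_id},
#'   \code{label}, \code{p_value} (from [reporterConcordance()] per
#'   strain), or NULL.
#' @return data.frame with one row per primary hit: \code{strain_id},
#'   \code{primary_class}, \code{secondary_class}, \code{concordance},
#'   \code{concordance_p}, \code{status} ("final", "dropped" or
#'   "pending").
#' @export
finalizeCandidates <- function(primary_summaries, secondary_summaries,
                               concordance = NULL) {
  hits <- primary_summaries[
    primary_summaries$classification %in% c("short", "long"), ,
    drop = FALSE]
  if (!nrow(hits))
    return(data.frame(strain_id = character(), primary_class = character(),
                      secondary_class = character(),
                      concordance = character(),
                      concordance_p = numeric(), status = character()))
  sec_cls <- secondary_summaries$classification[
    match(hits$strain_id, secondary_summaries$strain_id)]
  sec_cls[is.na(sec_cls)] <- "untested"
  conc <- rep("untested", nrow(hits))
  conc_p <- rep(NA_real_, nrow(hits))
  if (!is.null(concordance) && nrow(concordance)) {
    m <- match(hits$strain_id, concordance$strain_id)
    conc[!is.na(m)] <- concordance$label[m[!is.na(m)]]
    conc_p[!is.na(m)] <- concordance$p_value[m[!is.na(m)]]
  }
  status <- ifelse(sec_cls == "untested", "pending",
            ifelse(sec_cls == hits$classification, "final", "dropped"))
  out <- data.frame(strain_id = hits$strain_id,
                    primary_class = hits$classification,
                    secondary_class = sec_cls, concordance = conc,
                    concordance_p = conc_p, status = status)
  out[order(out$strain_id), , drop = FALSE]
}

#' Screen accounting: from catalogue to analysed knockouts
#'
#' @param n_listed loci in the catalogue.
#' @param n_unavailable loci without an available knockout.
#' @param n_failed_initial crosses that yielded no usable progeny.
#' @param n_recross_attempted failed crosses re-attempted with an
#'   alternative reporter location.
#' @param n_rescued re-crosses that recovered progeny.
#' @param n_arrhythmic_excluded analysed strains excluded as arrhythmic.
#' @return a [ScreenAccounting-class] with derived fields
#'   \code{nCrossed = nListed - nUnavailable} and
#'   \code{nAnalyzed = nCrossed - nFailedInitial + nRescued}.
#' @examples
#' screenAccounting(302, 45, 91, 18, 11)
#' @export
screenAccounting <- function(n_listed, n_unavailable, n_failed_initial,
                             n_recross_attempted, n_rescued,
                             n_arrhythmic_excluded = 0L) {
  new("ScreenAccounting",
      nListed = as.integer(n_listed),
      nUnavailable = as.integer(n_unavailable),
      nCrossed = as.integer(n_listed - n_unavailable),
      nFailedInitial = as.integer(n_failed_initial),
      nRecrossAttempted = as.integer(n_recross_attempted),
      nRescued = as.integer(n_rescued),
      nAnalyzed = as.integer(n_listed - n_unavailable - n_failed_initial +
                               n_rescued),
      nArrhythmicExcluded = as.integer(n_arrhythmic_excluded))
}
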
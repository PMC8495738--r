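#' @include AllClasses.R accessors.R pipeline.R
NULL

.trace_cols <- c("run_id", "plate_id", "well", "strain_id",
                 "genotype_class", "reporter_id", "time_h", "signal")

#' Read a long-format trace table
#'
#' Reads the screen's interchange format: CSV with one row per (well,
#' timepoint) and columns \code{run_id, plate_id, well, strain_id,
#' genotype_class, reporter_id, time_h, signal}. Rows may arrive out of
#' time order and are sorted; duplicated timestamps within a well are an
#' error.
#'
#' @param path CSV file.
#' @return a [TraceSet-class], one trace per (run, plate, well).
#' @seealso [writeTraces()]
#' @export
readTraces <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.trace_cols, names(df))
  if (length(missing_cols))
    stop("trace table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!is.numeric(df$time_h) || any(is.na(df$time_h)) || any(df$time_h < 0))
    stop("time_h must be numeric and >= 0")
  bad_class <- setdiff(unique(df$genotype_class),
                       c("WT", "KO", "parental"))
  if (length(bad_class))
    stop("unknown genotype_class value(s): ",
         paste(bad_class, collapse = ", "))
  key <- paste(df$run_id, df$plate_id, df$well, sep = "/")
  dup <- unique(key[duplicated(paste(key, df$time_h))])
  if (length(dup))
    stop("duplicated timestamps within well(s): ",
         paste(dup, collapse = ", "))
  traces <- lapply(split(df, key), function(w) {
    w <- w[order(w$time_h), , drop = FALSE]
    luminescenceTrace(times = w$time_h, values = w$signal,
                      run_id = w$run_id[1], plate_id = w$plate_id[1],
                      well = w$well[1], strain_id = w$strain_id[1],
                      genotype_class = w$genotype_class[1],
                      reporter_id = w$reporter_id[1])
  })
  traceSet(unname(traces))
}

#' Write traces as a long-format CSV
#'
#' Numeric columns are written with 17 significant digits so a
#' write/read round trip reproduces every value bit-exactly.
#'
#' @param traces a [TraceSet-class].
#' @param path output CSV file.
#' @return the path, invisibly.
#' @export
writeTraces <- function(traces, path) {
  df <- as.data.frame(traces)
  df$time_h <- sprintf("%.17g", df$time_h)
  df$signal <- sprintf("%.17g", df$signal)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write screen results to a directory
#'
#' Writes \code{results.tsv} (one row per strain x reporter with median
#' delta-tau, IQR, replicate counts, classification, concordance p-value
#' and final-candidate flag, ordered lexicographically by strain then
#' reporter) and \code{report.json} (tolerance intervals, candidate list,
#' stage counts and the accounting block). Output is deterministic:
#' re-running on the same input produces byte-identical files.
#'
#' @param result a [ScreenResult-class].
#' @param out_dir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
writeResults <- function(result, out_dir) {
  stopifnot(is(result, "ScreenResult"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  s <- result@summaries
  tsv <- data.frame(strain_id = character(), reporter = character(),
                    n = integer(), median_delta_tau_h = character(),
                    iqr_h = character(), rhythm_fraction = character(),
                    classification = character(),
                    concordance_p = character(),
                    final_candidate = logical())
  if (nrow(s)) {
    cp <- result@concordance$concordance_p[
      match(s$strain_id, result@concordance$strain_id)]
    tsv <- data.frame(
      strain_id = s$strain_id, reporter = s$reporter_id,
      n = s$n_replicates,
      median_delta_tau_h = sprintf("%.4f", s$median_delta_tau),
      iqr_h = sprintf("%.4f", s$iqr),
      rhythm_fraction = sprintf("%.3f", s$rhythm_fraction),
      classification = s$classification,
      concordance_p = ifelse(is.na(cp), "NA", sprintf("%.4g", cp)),
      final_candidate = s$strain_id %in% result@finalCandidates)
    tsv <- tsv[order(tsv$strain_id, tsv$reporter), , drop = FALSE]
  }
  tsv_path <- file.path(out_dir, "results.tsv")
  utils::write.table(tsv, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  interval_list <- function(iv) if (is.null(iv)) NULL else
    list(mean = iv@mean, sd = iv@sd, k = iv@k, lower = iv@lower,
         upper = iv@upper, shapiro_p = iv@shapiroP, n_wt = iv@nWt)
  acc <- result@accounting
  report <- list(
    n_traces = nrow(result@estimates),
    n_delta_tau = nrow(result@deltas),
    primary_interval = interval_list(result@primaryInterval),
    secondary_interval = interval_list(result@secondaryInterval),
    n_primary_hits = nrow(result@primaryHits),
    final_candidates = sort(result@finalCandidates),
    accounting = if (is.null(acc)) NULL else list(
      n_listed = acc@nListed, n_unavailable = acc@nUnavailable,
      n_crossed = acc@nCrossed, n_failed_initial = acc@nFailedInitial,
      n_recross_attempted = acc@nRecrossAttempted,
      n_rescued = acc@nRescued, n_analyzed = acc@nAnalyzed,
      n_arrhythmic_excluded = acc@nArrhythmicExcluded))
  json_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(tsv_path, json_path))
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys must be arguments of [pipelineConfig()]; an unknown key
#' is an error naming the key. An optional \code{simulation} block with
#' [screenConfig()] arguments configures the synthetic-screen generator
#' and is returned in the \code{"simulation"} attribute.
#'
#' @param path YAML file.
#' @return a [pipelineConfig()] with attribute \code{"simulation"} (a
#'   [screenConfig()] or NULL).
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  sim <- raw$simulation
  raw$simulation <- NULL
  known <- names(formals(pipelineConfig))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  if (!is.null(raw$circadian_window))
    raw$circadian_window <- as.numeric(unlist(raw$circadian_window))
  cfg <- do.call(pipelineConfig, raw)
  if (!is.null(sim)) {
    bad_sim <- setdiff(names(sim), names(formals(screenConfig)))
    if (length(bad_sim))
      stop("unknown simulation key(s): ", paste(bad_sim, collapse = ", "))
    if (!is.null(sim$planted_delta_tau))
      sim$planted_delta_tau <- as.numeric(unlist(sim$planted_delta_tau))
    attr(cfg, "simulation") <- do.call(screenConfig, sim)
  }
  cfg
}

#' Plot a luminescence trace
#'
#' @param x a [LuminescenceTrace-class].
#' @param y ignored.
#' @param ... passed to [graphics::plot()].
#' @return NULL, invisibly.
#' @export
setMethod("plot", signature("LuminescenceTrace", "missing"),
          function(x, y, ...) {
  graphics::plot(x@times, x@values, type = "l",
                 xlab = "hours in DD", ylab = "luminescence",
                 main = sprintf("%s (%s)", x@strainId, x@reporterId), ...)
  invisible(NULL)
})

#' Load the printed per-locus period changes of the worked example
#'
#' Returns the bundled table of 23 knockout loci with their reported median
#' period changes (hours): the package's worked-example fixture for
#' tolerance-interval hit classification.
#'
#' @return data.frame with columns \code{strain_id} and
#'   \code{median_delta_tau}.
#' @examples
#' head(candidateDeltaTau())
#' @export
candidateDeltaTau <- function() {
  path <- system.file("extdata", "candidate_delta_tau.tsv",
                      package = "CircaScreen", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
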
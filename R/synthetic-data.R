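#' @include AllClasses.R accessors.R
NULL

#' Describe the ground-truth signal model of one strain
#'
#' A strain truth record parameterises the generative model for a well:
#' \deqn{y(t) = \mathrm{baseline} + \mathrm{slope}\, t +
#'   A e^{-\lambda t} \cos\{2\pi (t - \phi)/\tau\} + \epsilon(t)}
#' with i.i.d. Gaussian noise. Arrhythmic strains (e.g. knockouts of core
#' clock components) have \code{amplitude = 0} and no period; low-signal
#' strains oscillate but at a small fraction of wild-type signal levels.
#'
#' @param strain_id strain identifier.
#' @param true_period free-running period tau in hours (> 0), or \code{NA}
#'   for arrhythmic strains.
#' @param amplitude oscillation amplitude A (signal units, >= 0); must be 0
#'   exactly when \code{class_label = "KO_arrhythmic"}.
#' @param damping_rate amplitude decay rate lambda, per hour (>= 0).
#' @param phase peak time phi in hours, in \code{[0, true_period)}.
#' @param baseline_level,baseline_slope linear baseline (signal units and
#'   signal units/hour).
#' @param noise_sd Gaussian noise SD (signal units, >= 0).
#' @param class_label one of \code{"WT"}, \code{"KO_rhythmic"},
#'   \code{"KO_arrhythmic"}, \code{"KO_low_signal"}.
#' @return a validated list of class \code{"StrainTruth"}.
#' @seealso [simulateTrace()], [screenConfig()]
#' @export
strainTruth <- function(strain_id, true_period = 21.76, amplitude = 100,
                        damping_rate = 0.01, phase = 0,
                        baseline_level = 200, baseline_slope = -0.3,
                        noise_sd = 10,
                        class_label = c("WT", "KO_rhythmic",
                                        "KO_arrhythmic", "KO_low_signal")) {
  class_label <- match.arg(class_label)
  if (!is.na(true_period) && true_period <= 0)
    stop("true_period must be > 0 (or NA for arrhythmic strains)")
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (damping_rate < 0) stop("damping_rate must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if ((amplitude == 0) != (class_label == "KO_arrhythmic"))
    stop("amplitude must be 0 exactly for class_label = 'KO_arrhythmic'")
  if (class_label == "KO_arrhythmic") true_period <- NA_real_
  if (!is.na(true_period) && (phase < 0 || phase >= true_period))
    stop("phase must lie in [0, true_period)")
  structure(list(strain_id = as.character(strain_id),
                 true_period = true_period, amplitude = amplitude,
                 damping_rate = damping_rate, phase = phase,
                 baseline_level = baseline_level,
                 baseline_slope = baseline_slope, noise_sd = noise_sd,
                 class_label = class_label),
            class = "StrainTruth")
}

#' Sampling schedule of a CCD camera run
#'
#' Imaging schedules of plate runs: 2 or 3 exposures per hour over 4-5 days
#' of constant darkness, starting at the transfer to darkness (t = 0).
#'
#' @param start_h first sampling time, hours since DD transfer.
#' @param duration_h total recording span in hours (> 0).
#' @param samples_per_hour exposures per hour (>= 1; the screens used 2
#'   or 3).
#' @return a list of class \code{"SamplingSchedule"} with a \code{times}
#'   vector of \code{duration_h * samples_per_hour + 1} strictly increasing
#'   timestamps.
#' @export
samplingSchedule <- function(start_h = 0, duration_h = 120,
                             samples_per_hour = 2) {
  if (duration_h <= 0) stop("duration_h must be > 0")
  if (samples_per_hour < 1) stop("samples_per_hour must be >= 1")
  times <- start_h + seq(0, duration_h, by = 1 / samples_per_hour)
  structure(list(start_h = start_h, duration_h = duration_h,
                 samples_per_hour = samples_per_hour, times = times),
            class = "SamplingSchedule")
}

#' Plate layout of a camera run
#'
#' @param run_id,plate_id identifiers.
#' @param wells data.frame with columns \code{well}, \code{strain_id},
#'   \code{reporter_id}, \code{genotype_class}. Well positions must be
#'   unique and at least one well must be a WT control (screens require
#'   internal WT controls on every plate).
#' @return a list of class \code{"PlateLayout"}.
#' @export
plateLayout <- function(run_id, plate_id, wells) {
  need <- c("well", "strain_id", "reporter_id", "genotype_class")
  if (!all(need %in% names(wells)))
    stop("wells needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(wells$well))
    stop("well positions must be unique within a plate")
  if (!any(wells$genotype_class == "WT"))
    stop("plate layout must contain at least one WT control well")
  structure(list(run_id = as.character(run_id),
                 plate_id = as.character(plate_id), wells = wells),
            class = "PlateLayout")
}

## deterministic model evaluation (no noise, no transient)
.cosine_signal <- function(truth, t) {
  y <- truth$baseline_level + truth$baseline_slope * t
  if (truth$amplitude > 0 && !is.na(truth$true_period))
    y <- y + truth$amplitude * exp(-truth$damping_rate * t) *
      cos(2 * pi * (t - truth$phase) / truth$true_period)
  y
}

#' Simulate one well's bioluminescence trace
#'
#' Evaluates the strain's damped-cosine signal model on the schedule's
#' timestamps, optionally adds an exponentially decaying transient bump
#' emulating light-to-dark transition noise (decayed essentially to zero
#' within the first 12 h), and adds i.i.d. Gaussian noise. Deterministic
#' for a fixed seed.
#'
#' @param truth a [strainTruth()] record.
#' @param schedule a [samplingSchedule()].
#' @param seed integer RNG seed.
#' @param transient_height height of the additive transition bump at t =
#'   start (signal units; 0 disables it).
#' @param transient_rate decay rate of the bump, per hour.
#' @param run_id,plate_id,well,reporter_id,genotype_class trace annotation.
#' @return a [LuminescenceTrace-class].
#' @examples
#' tr <- simulateTrace(strainTruth("WT"), samplingSchedule(), seed = 1)
#' tr
#' @export
simulateTrace <- function(truth, schedule, seed,
                          transient_height = 0, transient_rate = 0.5,
                          run_id = "run1", plate_id = "plate1",
                          well = "A01", reporter_id = "reporter",
                          genotype_class = NULL) {
  stopifnot(inherits(truth, "StrainTruth"),
            inherits(schedule, "SamplingSchedule"))
  if (missing(seed)) stop("a seed is required")
  set.seed(as.integer(seed))
  tr <- .simulate_trace_stream(truth, schedule, transient_height,
                               transient_rate, run_id, plate_id, well,
                               reporter_id, genotype_class)
  tr
}

## draws noise from the current RNG stream; used by simulateTrace (after
## set.seed) and by simulateRun/simulateScreen (single stream per run)
.simulate_trace_stream <- function(truth, schedule, transient_height = 0,
                                   transient_rate = 0.5, run_id = "run1",
                                   plate_id = "plate1", well = "A01",
                                   reporter_id = "reporter",
                                   genotype_class = NULL) {
  t <- schedule$times
  y <- .cosine_signal(truth, t - schedule$start_h)
  if (transient_height != 0)
    y <- y + transient_height * exp(-transient_rate * (t - schedule$start_h))
  if (truth$noise_sd > 0)
    y <- y + stats::rnorm(length(t), 0, truth$noise_sd)
  if (is.null(genotype_class))
    genotype_class <- if (truth$class_label == "WT") "WT" else "KO"
  luminescenceTrace(times = t, values = y, run_id = run_id,
                    plate_id = plate_id, well = well,
                    strain_id = truth$strain_id,
                    genotype_class = genotype_class,
                    reporter_id = reporter_id)
}

#' Simulate all wells of one camera run
#'
#' Simulates one trace per well of the layout. A run-level random period
#' offset (Gaussian, SD \code{run_jitter_sd}) is drawn once and added to the
#' true period of every rhythmic well in the run, emulating the inter-run
#' technical variation that per-run WT referencing is designed to absorb.
#'
#' @param layout a [plateLayout()]; every \code{strain_id} must have an
#'   entry in \code{truths}.
#' @param truths named list of [strainTruth()] records.
#' @param schedule a [samplingSchedule()].
#' @param seed integer RNG seed.
#' @param run_jitter_sd SD of the run-level period offset, hours.
#' @param well_jitter_sd SD of an independent per-well (biological
#'   replicate) period offset, hours; 0 disables it.
#' @param transient_height,transient_rate passed to the per-well signal
#'   model (transition bump).
#' @return a [TraceSet-class] with one trace per well.
#' @export
simulateRun <- function(layout, truths, schedule, seed,
                        run_jitter_sd = 0.1, well_jitter_sd = 0,
                        transient_height = 0, transient_rate = 0.5) {
  stopifnot(inherits(layout, "PlateLayout"))
  if (missing(seed)) stop("a seed is required")
  set.seed(as.integer(seed))
  .simulate_run_stream(layout, truths, schedule, run_jitter_sd,
                       well_jitter_sd, transient_height, transient_rate)
}

.simulate_run_stream <- function(layout, truths, schedule,
                                 run_jitter_sd = 0.1,
                                 well_jitter_sd = 0,
                                 transient_height = 0,
                                 transient_rate = 0.5) {
  wells <- layout$wells
  unknown <- setdiff(wells$strain_id, names(truths))
  if (length(unknown))
    stop("no truth entry for strain(s): ", paste(unknown, collapse = ", "))
  # jitter draws always advance the RNG stream so datasets generated with
  # different jitter SDs (including 0) stay comparable under a fixed seed
  offset <- stats::rnorm(1, 0, run_jitter_sd)
  traces <- vector("list", nrow(wells))
  for (i in seq_len(nrow(wells))) {
    truth <- truths[[wells$strain_id[i]]]
    if (!is.na(truth$true_period)) {
      wj <- stats::rnorm(1, 0, well_jitter_sd)
      truth$true_period <- truth$true_period + offset + wj
      truth$phase <- truth$phase %% truth$true_period
    }
    traces[[i]] <- .simulate_trace_stream(
      truth, schedule, transient_height, transient_rate,
      run_id = layout$run_id, plate_id = layout$plate_id,
      well = wells$well[i], reporter_id = wells$reporter_id[i],
      genotype_class = wells$genotype_class[i])
  }
  traceSet(traces)
}

#' Configuration of a simulated dual-reporter screen
#'
#' Defines the study conditions a simulated screen emulates: 96-well plates
#' with WT internal controls on every run, 2 samples/hour over 120 h of
#' constant darkness, wild-type free-running period 21.76 h, and knockout
#' strains with planted period shifts. Fractions of strains can be made
#' arrhythmic (zero amplitude, like core-clock knockouts), low-signal
#' (rhythmic at a few percent of WT signal), or discordant (planted shift
#' under the primary core-clock reporter only, absent under the output
#' reporter) to exercise the dual-reporter confirmation filter.
#'
#' @param n_strains number of knockout strains.
#' @param replicates progeny replicates per strain per reporter.
#' @param planted_delta_tau numeric, planted period changes in hours,
#'   recycled over strains (default 0 = null screen).
#' @param fraction_arrhythmic,fraction_low_signal,fraction_discordant
#'   fractions of strains assigned to each special class (must sum to <= 1).
#' @param wt_period wild-type free-running period, hours.
#' @param wt_per_run number of WT control wells per run.
#' @param wells_per_plate plate capacity (one plate per run).
#' @param amplitude,baseline_level,baseline_slope,noise_sd,damping_rate
#'   signal-model defaults shared by WT and KO strains; \code{noise_sd}
#'   scales with the strain's signal level (biological/shot noise).
#' @param noise_floor_sd absolute camera read-noise SD added in quadrature
#'   to the scaled noise for every well.
#' @param low_signal_scale factor applied to amplitude, baseline and
#'   scaled noise of low-signal strains.
#' @param run_jitter_sd SD of the run-level period offset, hours.
#' @param well_jitter_sd SD of the per-well biological period variation,
#'   hours; the default reproduces a WT delta-tau dispersion whose 3-SD
#'   tolerance interval spans roughly half an hour on each side.
#' @param duration_h,samples_per_hour sampling schedule.
#' @param transient_height,transient_rate light-to-dark transition bump.
#' @param reporters names of the primary (core-clock) and secondary
#'   (output) reporters.
#' @return a list of class \code{"ScreenConfig"}.
#' @seealso [simulateScreen()]
#' @export
screenConfig <- function(n_strains = 20, replicates = 8,
                         planted_delta_tau = 0,
                         fraction_arrhythmic = 0,
                         fraction_low_signal = 0,
                         fraction_discordant = 0,
                         wt_period = 21.76, wt_per_run = 8,
                         wells_per_plate = 96, amplitude = 100,
                         baseline_level = 200, baseline_slope = -0.3,
                         noise_sd = 10, noise_floor_sd = 1,
                         damping_rate = 0.01,
                         low_signal_scale = 0.02, run_jitter_sd = 0.1,
                         well_jitter_sd = 0.16,
                         duration_h = 120, samples_per_hour = 2,
                         transient_height = 150, transient_rate = 0.5,
                         reporters = c("frq_c-box", "con-10")) {
  if (replicates < 1) stop("replicates must be >= 1")
  if (n_strains < 0) stop("n_strains must be >= 0")
  fr <- c(fraction_arrhythmic, fraction_low_signal, fraction_discordant)
  if (any(fr < 0) || sum(fr) > 1)
    stop("class fractions must be >= 0 and sum to <= 1")
  if (length(reporters) != 2) stop("exactly two reporters are required")
  structure(as.list(environment()), class = "ScreenConfig")
}

#' Simulate a dual-reporter circadian screen with known ground truth
#'
#' Builds strain truths from the configuration, assigns strains to
#' 96-well-plate camera runs (each run carries its own WT control wells),
#' and simulates the full set of traces under both the primary core-clock
#' reporter and the secondary output reporter. Strain class assignment
#' (arrhythmic / low-signal / discordant) takes the first strains in order,
#' so the ground truth is fully deterministic given the configuration.
#'
#' @param config a [screenConfig()].
#' @param seed integer RNG seed; the whole screen is deterministic given
#'   \code{config} and \code{seed}.
#' @return list with elements \code{primary} and \code{secondary}
#'   ([TraceSet-class]s, one per reporter) and \code{truth}, a data.frame
#'   with columns \code{strain_id, class_label, true_delta_tau_h, reporter}
#'   (WT rows have \code{true_delta_tau_h = 0}).
#' @examples
#' sim <- simulateScreen(screenConfig(n_strains = 2, replicates = 2), seed = 1)
#' sim$truth
#' @export
simulateScreen <- function(config, seed) {
  stopifnot(inherits(config, "ScreenConfig"))
  if (missing(seed)) stop("a seed is required")
  cfg <- config
  schedule <- samplingSchedule(0, cfg$duration_h, cfg$samples_per_hour)
  empty_truth <- data.frame(strain_id = character(),
                            class_label = character(),
                            true_delta_tau_h = numeric(),
                            reporter = character())
  if (cfg$n_strains == 0)
    return(list(primary = traceSet(), secondary = traceSet(),
                truth = empty_truth))

  ids <- sprintf("KO%03d", seq_len(cfg$n_strains))
  planted <- rep_len(cfg$planted_delta_tau, cfg$n_strains)
  n_arr <- round(cfg$fraction_arrhythmic * cfg$n_strains)
  n_low <- round(cfg$fraction_low_signal * cfg$n_strains)
  n_dis <- round(cfg$fraction_discordant * cfg$n_strains)
  class_label <- rep("KO_rhythmic", cfg$n_strains)
  if (n_arr > 0) class_label[seq_len(n_arr)] <- "KO_arrhythmic"
  if (n_low > 0) class_label[n_arr + seq_len(n_low)] <- "KO_low_signal"
  discordant <- rep(FALSE, cfg$n_strains)
  if (n_dis > 0) discordant[n_arr + n_low + seq_len(n_dis)] <- TRUE
  planted[class_label == "KO_arrhythmic"] <- NA_real_

  make_truth <- function(i, delta) {
    cls <- class_label[i]
    scale <- if (cls == "KO_low_signal") cfg$low_signal_scale else 1
    strainTruth(ids[i],
                true_period = if (cls == "KO_arrhythmic") NA_real_
                              else cfg$wt_period + delta,
                amplitude = if (cls == "KO_arrhythmic") 0
                            else cfg$amplitude * scale,
                damping_rate = cfg$damping_rate, phase = 0,
                baseline_level = cfg$baseline_level * scale,
                baseline_slope = cfg$baseline_slope * scale,
                noise_sd = sqrt((cfg$noise_sd * scale)^2 +
                                  cfg$noise_floor_sd^2),
                class_label = cls)
  }
  wt_truth <- strainTruth("WT", true_period = cfg$wt_period,
                          amplitude = cfg$amplitude,
                          damping_rate = cfg$damping_rate, phase = 0,
                          baseline_level = cfg$baseline_level,
                          baseline_slope = cfg$baseline_slope,
                          noise_sd = sqrt(cfg$noise_sd^2 +
                                            cfg$noise_floor_sd^2),
                          class_label = "WT")

  ko_per_run <- cfg$wells_per_plate - cfg$wt_per_run
  if (ko_per_run < 1) stop("wells_per_plate must exceed wt_per_run")

  simulate_reporter <- function(reporter, deltas) {
    truths <- c(list(WT = wt_truth),
                stats::setNames(lapply(seq_len(cfg$n_strains), function(i)
                  make_truth(i, if (is.na(deltas[i])) 0 else deltas[i])),
                  ids))
    ko_wells <- rep(ids, each = cfg$replicates)
    n_runs <- max(1L, ceiling(length(ko_wells) / ko_per_run))
    traces <- list()
    for (r in seq_len(n_runs)) {
      lo <- (r - 1L) * ko_per_run + 1L
      hi <- min(r * ko_per_run, length(ko_wells))
      run_strains <- c(rep("WT", cfg$wt_per_run), ko_wells[lo:hi])
      wells <- data.frame(
        well = sprintf("%s%02d", LETTERS[((seq_along(run_strains) - 1) %/%
                                            12) + 1],
                       ((seq_along(run_strains) - 1) %% 12) + 1),
        strain_id = run_strains, reporter_id = reporter,
        genotype_class = ifelse(run_strains == "WT", "WT", "KO"))
      layout <- plateLayout(sprintf("%s_run%02d", reporter, r),
                            sprintf("plate%02d", r), wells)
      ts <- .simulate_run_stream(layout, truths, schedule,
                                 cfg$run_jitter_sd, cfg$well_jitter_sd,
                                 cfg$transient_height, cfg$transient_rate)
      traces <- c(traces, ts@traces)
    }
    traceSet(traces)
  }

  set.seed(as.integer(seed))
  primary <- simulate_reporter(cfg$reporters[1], planted)
  sec_deltas <- ifelse(discordant, 0, planted)
  secondary <- simulate_reporter(cfg$reporters[2], sec_deltas)

  truth <- rbind(
    data.frame(strain_id = c("WT", ids), class_label = c("WT", class_label),
               true_delta_tau_h = c(0, planted),
               reporter = cfg$reporters[1]),
    data.frame(strain_id = c("WT", ids), class_label = c("WT", class_label),
               true_delta_tau_h = c(0, sec_deltas),
               reporter = cfg$reporters[2]))
  list(primary = primary, secondary = secondary, truth = truth)
}

#' Write a ground-truth table as TSV
#'
#' @param truth the \code{truth} data.frame from [simulateScreen()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
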
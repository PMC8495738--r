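test_that("noiseless traces equal the closed-form model at every timestamp", {
  truth <- strainTruth("X", true_period = 24, amplitude = 100,
                       damping_rate = 0, phase = 3, baseline_level = 50,
                       baseline_slope = 0.2, noise_sd = 0,
                       class_label = "KO_rhythmic")
  sch <- samplingSchedule(0, 96, 2)
  tr <- simulateTrace(truth, sch, seed = 7)
  expect_length(times(tr), 96 * 2 + 1)
  expected <- 50 + 0.2 * sch$times +
    100 * cos(2 * pi * (sch$times - 3) / 24)
  expect_equal(signalValues(tr), expected, tolerance = 1e-12)

  # damping enters as an exponential envelope
  truth$damping_rate <- 0.02
  tr2 <- simulateTrace(truth, sch, seed = 7)
  expected2 <- 50 + 0.2 * sch$times + 100 * exp(-0.02 * sch$times) *
    cos(2 * pi * (sch$times - 3) / 24)
  expect_equal(signalValues(tr2), expected2, tolerance = 1e-12)
})

test_that("trace simulation is deterministic for a fixed seed", {
  truth <- strainTruth("WT")
  sch <- samplingSchedule()
  a <- simulateTrace(truth, sch, seed = 11, transient_height = 150)
  b <- simulateTrace(truth, sch, seed = 11, transient_height = 150)
  expect_identical(signalValues(a), signalValues(b))
  c <- simulateTrace(truth, sch, seed = 12, transient_height = 150)
  expect_false(identical(signalValues(a), signalValues(c)))
})

test_that("arrhythmic truths give constant-plus-noise traces", {
  truth <- strainTruth("arr", amplitude = 0, baseline_slope = 0,
                       noise_sd = 0, class_label = "KO_arrhythmic")
  tr <- simulateTrace(truth, samplingSchedule(0, 48, 2), seed = 1)
  expect_true(all(signalValues(tr) == signalValues(tr)[1]))
})

test_that("invalid generator parameters are rejected", {
  expect_error(strainTruth("x", noise_sd = -1), "noise_sd")
  expect_error(strainTruth("x", true_period = -2), "true_period")
  expect_error(strainTruth("x", amplitude = 0), "KO_arrhythmic")
  expect_error(strainTruth("x", amplitude = 5,
                           class_label = "KO_arrhythmic"), "amplitude")
  expect_error(strainTruth("x", phase = 30), "phase")
  expect_error(samplingSchedule(duration_h = 0), "duration")
  expect_error(samplingSchedule(samples_per_hour = 0), "samples_per_hour")
})

test_that("run simulation enforces WT controls and shares the run offset", {
  sch <- samplingSchedule(0, 48, 2)
  truths <- list(WT = strainTruth("WT", noise_sd = 0, damping_rate = 0,
                                  baseline_slope = 0),
                 ko = strainTruth("ko", true_period = 23, noise_sd = 0,
                                  damping_rate = 0, baseline_slope = 0,
                                  class_label = "KO_rhythmic"))
  wells <- data.frame(well = sprintf("A%02d", 1:8),
                      strain_id = c("WT", "WT", rep("ko", 6)),
                      reporter_id = "rep",
                      genotype_class = c("WT", "WT", rep("KO", 6)))
  layout <- plateLayout("r1", "p1", wells)
  ts <- simulateRun(layout, truths, sch, seed = 5, run_jitter_sd = 0)
  expect_length(ts, 8)
  # noiseless, zero jitter: replicate wells of one strain are identical
  expect_identical(signalValues(ts[[3]]), signalValues(ts[[4]]))
  expect_identical(signalValues(ts[[1]]), signalValues(ts[[2]]))

  # zero run jitter: WT wells identical across runs too
  layout2 <- plateLayout("r2", "p1", wells)
  ts2 <- simulateRun(layout2, truths, sch, seed = 99, run_jitter_sd = 0)
  expect_identical(signalValues(ts[[1]]), signalValues(ts2[[1]]))

  no_wt <- wells; no_wt$genotype_class <- "KO"; no_wt$strain_id <- "ko"
  expect_error(plateLayout("r1", "p1", no_wt), "WT control")
  bad <- wells; bad$strain_id[3] <- "missing"
  expect_error(simulateRun(plateLayout("r1", "p1", bad), truths, sch,
                           seed = 1), "missing")
})

test_that("screen simulation keeps truth bookkeeping exact", {
  planted <- c(0, -1.2, 0.8, 0)
  cfg <- tiny_screen_config(planted_delta_tau = planted)
  sim <- simulateScreen(cfg, seed = 3)
  tt <- sim$truth
  prim <- tt[tt$reporter == "frq_c-box" & tt$strain_id != "WT", ]
  expect_equal(prim$true_delta_tau_h[order(prim$strain_id)], planted)
  expect_true(all(tt$true_delta_tau_h[tt$strain_id == "WT"] == 0))

  # discordant strains carry their shift under the primary reporter only
  cfg2 <- screenConfig(n_strains = 4, replicates = 2, wt_per_run = 4,
                       duration_h = 96, planted_delta_tau = 1,
                       fraction_discordant = 0.5)
  tt2 <- simulateScreen(cfg2, seed = 3)$truth
  dis <- tt2[tt2$strain_id %in% c("KO001", "KO002"), ]
  expect_true(all(dis$true_delta_tau_h[dis$reporter == "frq_c-box"] == 1))
  expect_true(all(dis$true_delta_tau_h[dis$reporter == "con-10"] == 0))

  # determinism of the full screen
  a <- simulateScreen(cfg, seed = 8)
  b <- simulateScreen(cfg, seed = 8)
  expect_identical(as.data.frame(a$primary), as.data.frame(b$primary))
  expect_identical(as.data.frame(a$secondary), as.data.frame(b$secondary))

  # degenerate and invalid configurations
  empty <- simulateScreen(screenConfig(n_strains = 0), seed = 1)
  expect_length(empty$primary, 0)
  expect_equal(nrow(empty$truth), 0)
  expect_error(screenConfig(replicates = 0), "replicates")
  expect_error(screenConfig(fraction_arrhythmic = 0.7,
                            fraction_low_signal = 0.6), "fractions")
})

test_that("every run of a simulated screen contains WT replicates", {
  sim <- simulateScreen(tiny_screen_config(), seed = 2)
  df <- as.data.frame(sim$primary)
  for (r in unique(df$run_id))
    expect_true(any(df$genotype_class[df$run_id == r] == "WT"))
})
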
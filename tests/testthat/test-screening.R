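est_row <- function(strain, run, period, label = "rhythmic",
                    gclass = "KO", reporter = "rep") {
  data.frame(run_id = run, plate_id = "p1", well = "A01",
             strain_id = strain, genotype_class = gclass,
             reporter_id = reporter, period = period,
             period_se = 0.05, amplitude = 50, rae = 0.1,
             rhythm_label = label, raw_mean = 200, normalized = FALSE)
}

test_that("run WT references average rhythmic WT periods per run", {
  est <- rbind(est_row("WT", "r1", 21.7, gclass = "WT"),
               est_row("WT", "r1", 21.8, gclass = "WT"),
               est_row("ko", "r1", 20.0))
  refs <- runWTReference(est)
  expect_equal(refs$wt_reference, 21.75)
  expect_equal(refs$n_wt, 2L)

  single <- est_row("WT", "r1", 21.76, gclass = "WT")
  expect_equal(runWTReference(single)$wt_reference, 21.76)

  no_wt <- est_row("ko", "r1", 20)
  expect_error(runWTReference(no_wt), "WT control")

  # a run whose WT are all arrhythmic is dropped with a warning
  mixed <- rbind(est, est_row("WT", "r2", NA, label = "arrhythmic",
                              gclass = "WT"),
                 est_row("ko2", "r2", 22))
  expect_warning(refs2 <- runWTReference(mixed), "r2")
  expect_equal(refs2$run_id, "r1")
})

test_that("delta-tau is the replicate period minus its run reference", {
  est <- rbind(est_row("WT", "r1", 21.76, gclass = "WT"),
               est_row("ring6", "r1", 19.88),
               est_row("cbf1", "r1", 23.14),
               est_row("same", "r1", 21.76),
               est_row("dead", "r1", NA, label = "arrhythmic"))
  dt <- computeDeltaTau(est, runWTReference(est))
  get <- function(s) dt$delta_tau[dt$strain_id == s]
  expect_equal(get("ring6"), -1.88)
  expect_equal(get("cbf1"), 1.38)
  expect_equal(get("same"), 0)
  expect_false("dead" %in% dt$strain_id)
  expect_equal(attr(dt, "skipped")[["arrhythmic"]], 1L)
})

test_that("the 3-SD wild-type interval reproduces the half-width arithmetic", {
  # construct a WT sample with mean 0 and SD exactly 0.1633
  raw <- c(-1.8, -1.1, -0.4, -0.2, 0.1, 0.3, 0.5, 0.9, 1.7)
  wt <- (raw - mean(raw)) / sd(raw) * 0.1633
  iv <- wtToleranceInterval(wt, k = 3)
  expect_equal(iv@sd, 0.1633, tolerance = 1e-12)
  expect_equal(unname(diff(intervalBounds(iv))) / 2, 0.49, tolerance = 0.005)
  expect_equal(round((iv@upper - iv@lower) / 2, 2), 0.49)
  expect_false(is.na(iv@shapiroP))

  expect_warning(zero <- wtToleranceInterval(rep(0.1, 5)), "zero-width")
  expect_equal(unname(intervalBounds(zero)), c(0.1, 0.1))
  expect_error(wtToleranceInterval(c(0, 0.1)), "at least 3")

  # strongly non-normal WT population triggers the normality warning
  set.seed(10)
  skewed <- rexp(50)
  expect_warning(wtToleranceInterval(skewed), "Shapiro")
})

test_that("strain summaries use outlier-robust medians", {
  s <- summarizeStrain(c(-0.9, -1.0, -0.8), "a")
  expect_equal(s$median_delta_tau, -0.9)
  expect_equal(s$iqr, 0.1)
  expect_equal(s$classification, "unclassified")

  robust <- summarizeStrain(c(-0.5, -0.5, 4.0), "b")
  expect_equal(robust$median_delta_tau, -0.5)

  few <- summarizeStrain(c(-0.5, -0.4), "c", min_n = 3)
  expect_equal(few$classification, "insufficient_n")
})

test_that("hit calling is strict at the interval bounds and monotone", {
  # a clean interval centred at 0 with half-width 3 * 0.1633 = 0.49
  wt <- c(-1, 0, 1) / sd(c(-1, 0, 1)) * 0.1633
  iv <- wtToleranceInterval(wt, k = 3)
  mk <- function(med, strain) {
    s <- summarizeStrain(rep(med, 4), strain)
    s$rhythm_fraction <- 1; s
  }
  sums <- rbind(mk(0.50, "znf41"), mk(0, "null"), mk(iv@upper, "edge"),
                mk(-0.60, "short1"))
  out <- callPrimaryHits(sums, iv)
  cls <- setNames(out$classification, out$strain_id)
  expect_equal(unname(cls["znf41"]), "long")
  expect_equal(unname(cls["null"]), "within_interval")
  expect_equal(unname(cls["edge"]), "within_interval")  # strict bound
  expect_equal(unname(cls["short1"]), "short")
  expect_equal(sort(attr(out, "hits")$strain_id), c("short1", "znf41"))

  # arrhythmic strains are never hits regardless of median
  arr <- mk(2.5, "arr"); arr$rhythm_fraction <- 0.2
  expect_equal(callPrimaryHits(arr, iv)$classification, "arrhythmic")

  # monotonicity: anything at least as extreme as a hit is a hit
  set.seed(11)
  meds <- runif(50, -2, 2)
  sums2 <- do.call(rbind, lapply(seq_along(meds), function(i)
    mk(meds[i], paste0("s", i))))
  out2 <- callPrimaryHits(sums2, iv)
  hit <- out2$classification %in% c("short", "long")
  for (i in which(hit)) {
    more_extreme <- sign(meds) == sign(meds[i]) & abs(meds) >= abs(meds[i])
    expect_true(all(hit[more_extreme]))
  }
})

test_that("reporter concordance matches a first-principles Welch test", {
  expect_equal(reporterConcordance(rep(1, 3), rep(1, 3))$label,
               "concordant")
  set.seed(12)
  a <- rnorm(8, -0.9, 0.1); b <- rnorm(8, 0, 0.1)
  cc <- reporterConcordance(a, b)
  expect_equal(cc$label, "discordant")
  expect_equal(cc$p_value, welch_p(a, b), tolerance = 1e-12)

  c2 <- rnorm(8, -0.7, 0.1); d2 <- rnorm(8, -0.7, 0.1)
  cc2 <- reporterConcordance(c2, d2)
  expect_equal(cc2$label, "concordant")
  expect_equal(cc2$p_value, welch_p(c2, d2), tolerance = 1e-12)

  expect_equal(reporterConcordance(1, c(1, 2))$label, "untested")
})

test_that("final candidates need both reporters shifted the same way", {
  mk <- function(strain, cls)
    data.frame(strain_id = strain, reporter_id = "x",
               median_delta_tau = 0, iqr = 0, n_replicates = 4,
               rhythm_fraction = 1, low_signal_fraction = 0,
               classification = cls)
  prim <- rbind(mk("a", "short"), mk("b", "long"), mk("c", "short"),
                mk("d", "short"), mk("e", "within_interval"))
  sec <- rbind(mk("a", "short"), mk("b", "within_interval"),
               mk("c", "long"))
  conc <- data.frame(strain_id = c("a", "b", "c"),
                     label = c("discordant", "concordant", "concordant"),
                     p_value = c(0.01, 0.5, 0.6))
  fin <- finalizeCandidates(prim, sec, conc)
  st <- setNames(fin$status, fin$strain_id)
  expect_equal(unname(st["a"]), "final")    # discordant t-test, both short
  expect_equal(unname(st["b"]), "dropped")  # secondary within interval
  expect_equal(unname(st["c"]), "dropped")  # opposite signs
  expect_equal(unname(st["d"]), "pending")  # no secondary data
  expect_false("e" %in% fin$strain_id)      # never was a hit

  none <- finalizeCandidates(prim[prim$classification == "within_interval", ],
                             sec, conc)
  expect_equal(nrow(none), 0)
})

test_that("screen accounting derives the funnel counts", {
  acc <- screenAccounting(302, 45, 91, 18, 11)
  expect_equal(acc@nCrossed, 257L)
  expect_equal(acc@nAnalyzed, 177L)

  simple <- screenAccounting(100, 10, 0, 0, 0)
  expect_equal(simple@nAnalyzed, simple@nCrossed)

  expect_error(screenAccounting(100, 10, 5, 3, 4), "nRescued")
  expect_error(screenAccounting(100, 10, 5, 8, 2), "nRecrossAttempted")
  expect_error(screenAccounting(100, 110, 5, 2, 1), "nUnavailable")
})

test_that("delta-tau absorbs run-level period offsets exactly", {
  # noiseless screens differing only in run jitter give identical delta-tau
  base <- list(n_strains = 6, replicates = 3, wt_per_run = 4,
               duration_h = 96, noise_sd = 0, noise_floor_sd = 0,
               damping_rate = 0, well_jitter_sd = 0, transient_height = 0,
               planted_delta_tau = c(0, 0, -1.5, 0, 1.2, 0))
  cfg0 <- do.call(screenConfig, c(base, run_jitter_sd = 0))
  cfg1 <- do.call(screenConfig, c(base, run_jitter_sd = 0.5))
  # noiseless WT wells give a zero-width interval; irrelevant here
  res0 <- suppressWarnings(runScreen(simulateScreen(cfg0, seed = 21)$primary))
  res1 <- suppressWarnings(runScreen(simulateScreen(cfg1, seed = 21)$primary))
  d0 <- res0@deltas[res0@deltas$genotype_class == "KO", ]
  d1 <- res1@deltas[res1@deltas$genotype_class == "KO", ]
  expect_equal(d1$delta_tau[order(d1$strain_id, d1$well)],
               d0$delta_tau[order(d0$strain_id, d0$well)],
               tolerance = 1e-4)
  truth <- simulateScreen(cfg1, seed = 21)$truth
  tt <- truth[truth$reporter == "frq_c-box" & truth$strain_id != "WT", ]
  med <- tapply(d1$delta_tau, d1$strain_id, median)
  expect_equal(as.vector(med[tt$strain_id]), tt$true_delta_tau_h,
               tolerance = 1e-3)
})
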
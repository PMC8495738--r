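test_that("periodogram seeding finds spectral peaks where brute force does", {
  t <- seq(0, 96, by = 0.5)
  tr <- make_cosine_trace(tau = 22, amp = 50, times = t)
  seeds <- periodogramSeeds(detrendTrace(tr))
  # oracle: dense least-squares scan over candidate periods
  oracle <- bf_best_period(t, signalValues(tr), seq(15, 30, 0.01))
  # within one frequency bin of the zero-padded grid
  span <- diff(range(t))
  bin_tol <- seeds$period[1]^2 / (4 * span)
  expect_lt(abs(seeds$period[1] - oracle), bin_tol + 0.01)
  expect_lt(abs(seeds$period[1] - 22), bin_tol)

  two <- luminescenceTrace(times = t,
                           values = 50 * cos(2 * pi * t / 22) +
                             30 * cos(2 * pi * t / 8))
  s2 <- periodogramSeeds(detrendTrace(two))
  expect_lt(abs(sort(s2$period[1:2], decreasing = TRUE)[1] - 22), 1)
  expect_lt(abs(sort(s2$period[1:2], decreasing = TRUE)[2] - 8), 0.2)

  zero <- luminescenceTrace(times = t, values = rep(0, length(t)))
  expect_equal(nrow(periodogramSeeds(zero)), 0)

  set.seed(4)
  noise <- luminescenceTrace(times = t, values = rnorm(length(t)))
  sn <- periodogramSeeds(detrendTrace(noise))
  # white noise: nothing dominant - every candidate is low-power-flagged
  expect_true(nrow(sn) == 0 || all(sn$low_power))

  expect_error(periodogramSeeds(
    luminescenceTrace(times = 1:4, values = rnorm(4))), "8 samples")
})

test_that("irregular sampling is handled by the least-squares periodogram", {
  set.seed(9)
  t <- sort(runif(150, 0, 96))
  tr <- luminescenceTrace(times = t, values = 40 * cos(2 * pi * t / 21))
  seeds <- periodogramSeeds(detrendTrace(tr))
  expect_lt(abs(seeds$period[1] - 21), 0.5)
  est <- estimatePeriod(detrendTrace(tr))
  expect_equal(period(est), 21, tolerance = 1e-4)
})

test_that("cosine NLLS recovers noiseless parameters and honours contracts", {
  t <- seq(0, 96, by = 0.5)
  tr <- make_cosine_trace(tau = 24, amp = 100, phase = 5, times = t)
  seeds <- data.frame(period = 24 * 1.08, amplitude = 90, phase = 4.5)
  fit <- fitCosineModel(detrendTrace(tr), seeds, 1)
  cmp <- components(fit)
  expect_equal(cmp$period, 24, tolerance = 1e-3)
  expect_equal(cmp$amplitude, 100, tolerance = 1e-3)
  expect_equal(cmp$phase, 5, tolerance = 1e-3)
  expect_lt(fit@sse, 1e-12 * var(signalValues(tr)) * length(t))

  # trend-only fit reduces to the normal-equations line
  noisy <- make_cosine_trace(tau = 24, amp = 30, times = t, noise_sd = 10,
                             seed = 5, intercept = 7, slope = 0.3)
  f0 <- fitCosineModel(noisy, seeds, 0)
  X <- cbind(1, t)
  beta <- solve(crossprod(X), crossprod(X, signalValues(noisy)))
  expect_equal(f0@intercept, beta[1], tolerance = 1e-8)
  expect_equal(f0@slope, beta[2], tolerance = 1e-8)
  expect_equal(f0@sse,
               sum((signalValues(noisy) - X %*% beta)^2),
               tolerance = 1e-8)

  # optimization contract: fitted SSE never exceeds the seed SSE
  dtr <- detrendTrace(noisy)
  sd_seeds <- periodogramSeeds(dtr)
  fit1 <- fitCosineModel(dtr, sd_seeds, 1)
  seed_model <- sd_seeds$amplitude[1] *
    cos(2 * pi * (times(dtr) - sd_seeds$phase[1]) / sd_seeds$period[1])
  line <- lm.fit(cbind(1, times(dtr)), signalValues(dtr) - seed_model)
  expect_lte(fit1@sse, sum(line$residuals^2) + 1e-8)

  expect_error(fitCosineModel(dtr, sd_seeds[0, ], 1), "seed")
})

test_that("period estimation matches a dense grid-search oracle", {
  t <- seq(0, 96, by = 0.5)
  for (tau in c(18.3, 21.76, 30)) {
    tr <- make_cosine_trace(tau = tau, amp = 80, times = t)
    est <- estimatePeriod(detrendTrace(tr))
    grid <- seq(16, 32, by = 0.01)
    oracle <- bf_best_period(t, signalValues(tr), grid)
    expect_lt(abs(period(est) - oracle), 0.011)
    expect_equal(period(est), tau, tolerance = 1e-4)
    expect_equal(rhythmLabel(est), "rhythmic")
  }
})

test_that("white noise and out-of-window signals are called arrhythmic", {
  t <- seq(0, 96, by = 0.5)
  set.seed(6)
  noise <- luminescenceTrace(times = t, values = rnorm(length(t), sd = 10))
  est <- estimatePeriod(detrendTrace(noise))
  expect_equal(rhythmLabel(est), "arrhythmic")
  expect_true(is.na(period(est)))

  fast <- make_cosine_trace(tau = 8, amp = 50, times = t)
  expect_equal(rhythmLabel(estimatePeriod(detrendTrace(fast))),
               "arrhythmic")
})

test_that("estimates are scale and time-shift equivariant", {
  t <- seq(0, 96, by = 0.5)
  base <- make_cosine_trace(tau = 21.5, amp = 60, phase = 2, times = t,
                            noise_sd = 6, seed = 8)
  ref <- estimatePeriod(detrendTrace(base))
  ref_phase <- components(ref@fit)$phase[1]
  for (c in c(0.05, 4, 250)) {
    scaled <- luminescenceTrace(times = t, values = c * signalValues(base))
    es <- estimatePeriod(detrendTrace(scaled))
    expect_equal(period(es), period(ref), tolerance = 1e-8)
    expect_equal(rae(es), rae(ref), tolerance = 1e-6)
    expect_equal(amplitude(es), c * amplitude(ref), tolerance = 1e-6)
    expect_equal(components(es@fit)$phase[1], ref_phase, tolerance = 1e-6)
  }
  for (shift in c(3, 12.5)) {
    moved <- luminescenceTrace(times = t + shift,
                               values = signalValues(base))
    em <- estimatePeriod(detrendTrace(moved))
    expect_equal(period(em), period(ref), tolerance = 1e-6)
    expect_equal(components(em@fit)$phase[1] %% period(ref),
                 (ref_phase + shift) %% period(ref), tolerance = 1e-4)
  }
})

test_that("adding components never increases the SSE", {
  t <- seq(0, 96, by = 0.5)
  tr <- luminescenceTrace(times = t,
                          values = 50 * cos(2 * pi * t / 22) +
                            20 * cos(2 * pi * t / 8) +
                            rnorm(length(t), sd = 5))
  dtr <- detrendTrace(tr)
  seeds <- periodogramSeeds(dtr)
  n_max <- min(3, nrow(seeds))
  sses <- vapply(0:n_max, function(k)
    fitCosineModel(dtr, seeds, k)@sse, numeric(1))
  expect_true(all(diff(sses) <= 1e-6))
})

test_that("the undamped fit still recovers the period of damped traces", {
  truth <- strainTruth("WT", damping_rate = 0.015, noise_sd = 0)
  tr <- simulateTrace(truth, samplingSchedule(0, 120, 2), seed = 1)
  est <- estimatePeriod(detrendTrace(trimWindow(tr)))
  expect_equal(period(est), 21.76, tolerance = 0.05)
  expect_equal(rhythmLabel(est), "rhythmic")
})

test_that("rhythmicity classification follows the rule table", {
  expect_equal(classifyRhythmicity(rae = 0.2, period = 22), "rhythmic")
  expect_equal(classifyRhythmicity(rae = NA, period = NA), "arrhythmic")
  expect_equal(classifyRhythmicity(rae = 0.8, period = 22), "arrhythmic")
  expect_equal(classifyRhythmicity(rae = 0.2, period = 40), "arrhythmic")
  expect_equal(
    classifyRhythmicity(rae = NA, period = NA, raw_mean = 2,
                        wt_raw_mean = 100, normalized_rhythmic = TRUE),
    "low_signal")
  expect_equal(
    classifyRhythmicity(rae = NA, period = NA, raw_mean = 2,
                        wt_raw_mean = 100, normalized_rhythmic = FALSE),
    "arrhythmic")
})
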
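test_that("window trimming keeps exactly the interior interval", {
  tr <- luminescenceTrace(times = 0:120, values = rnorm(121))
  out <- trimWindow(tr, 12, 12)
  expect_length(times(out), 97)
  expect_equal(range(times(out)), c(12, 108))
  expect_equal(processingLog(out)[[1]]$name, "trim_window")

  expect_identical(times(trimWindow(tr, 0, 0)), times(tr))
  short <- luminescenceTrace(times = 0:20, values = rnorm(21))
  expect_error(trimWindow(short, 12, 12), "more than 24 h")
})

test_that("successive trims compose additively", {
  tr <- luminescenceTrace(times = seq(0, 120, 0.5), values = rnorm(241))
  a <- trimWindow(trimWindow(tr, 5, 3), 7, 9)
  b <- trimWindow(tr, 12, 12)
  expect_equal(times(a), times(b))
  expect_equal(signalValues(a), signalValues(b))
})

test_that("detrending removes exactly the span of the trend basis", {
  t <- seq(0, 100, 0.5)
  ramp <- luminescenceTrace(times = t, values = 3 + 0.5 * t)
  res <- signalValues(detrendTrace(ramp))
  # oracle: residuals of an independent OLS line fit
  oracle <- residuals(lm((3 + 0.5 * t) ~ t))
  expect_equal(res, unname(oracle), tolerance = 1e-9)
  expect_lt(max(abs(res)), 1e-9)

  flat <- luminescenceTrace(times = t, values = rep(4, length(t)))
  expect_lt(max(abs(signalValues(detrendTrace(flat)))), 1e-12)

  # adding any linear function leaves linear-detrend residuals unchanged
  set.seed(1)
  y <- rnorm(length(t))
  base <- signalValues(detrendTrace(luminescenceTrace(times = t, values = y)))
  for (ab in list(c(5, 0), c(-2, 1.3), c(100, -0.7))) {
    shifted <- luminescenceTrace(times = t, values = y + ab[1] + ab[2] * t)
    expect_equal(signalValues(detrendTrace(shifted)), base,
                 tolerance = 1e-9)
  }

  # idempotency
  once <- detrendTrace(luminescenceTrace(times = t, values = y))
  twice <- detrendTrace(once)
  expect_equal(signalValues(twice), signalValues(once), tolerance = 1e-9)

  # polynomial detrend removes a quadratic exactly
  quad <- luminescenceTrace(times = t, values = 1 + t - 0.02 * t^2)
  expect_lt(max(abs(signalValues(
    detrendTrace(quad, "polynomial", 2)))), 1e-8)
  expect_error(detrendTrace(luminescenceTrace(times = 0:2, values = 1:3),
                            "polynomial", 2), "samples")
})

test_that("mean normalization has mean one and is scale invariant", {
  tr <- luminescenceTrace(times = 0:47, values = rep(5, 48))
  expect_equal(signalValues(normalizeToMean(tr)), rep(1, 48))

  set.seed(2)
  y <- 100 + rnorm(48, sd = 10)
  tr2 <- luminescenceTrace(times = 0:47, values = y)
  expect_equal(mean(signalValues(normalizeToMean(tr2))), 1,
               tolerance = 1e-12)
  for (c in c(0.01, 3, 1e4)) {
    scaled <- luminescenceTrace(times = 0:47, values = c * y)
    expect_equal(signalValues(normalizeToMean(scaled)),
                 signalValues(normalizeToMean(tr2)), tolerance = 1e-12)
  }

  detr <- detrendTrace(tr2)
  expect_error(normalizeToMean(detr), "near-zero mean")
})

test_that("preprocessing preserves timestamps and records provenance", {
  tr <- make_cosine_trace(intercept = 100, slope = 1, noise_sd = 5,
                          seed = 3)
  out <- detrendTrace(normalizeToMean(trimWindow(tr)))
  expect_equal(times(out), times(trimWindow(tr)))
  expect_equal(vapply(processingLog(out), `[[`, "", "name"),
               c("trim_window", "normalize_to_mean", "detrend"))
})
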
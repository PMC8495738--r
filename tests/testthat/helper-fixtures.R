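# fixtures built in code; no data files

# plain cosine-plus-line trace on an explicit time grid
make_cosine_trace <- function(tau = 22, amp = 50, phase = 0, intercept = 0,
                              slope = 0, times = seq(0, 96, by = 0.5),
                              noise_sd = 0, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  y <- intercept + slope * times +
    amp * cos(2 * pi * (times - phase) / tau)
  if (noise_sd > 0) y <- y + rnorm(length(times), 0, noise_sd)
  luminescenceTrace(times = times, values = y, ...)
}

# independent brute-force oracle: least-squares power over a period grid
# (used to cross-check the periodogram and the NLLS fit)
bf_best_period <- function(times, values, periods) {
  y <- values - mean(values)
  sse <- vapply(periods, function(tau) {
    X <- cbind(1, cos(2 * pi * times / tau), sin(2 * pi * times / tau))
    sum(lm.fit(X, y)$residuals^2)
  }, numeric(1))
  periods[which.min(sse)]
}

# Welch t-test computed from first principles (oracle for concordance)
welch_p <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  2 * pt(-abs(tstat), df)
}

# small raw-trace screen defaults kept light for unit tests
tiny_screen_config <- function(...) {
  screenConfig(n_strains = 4, replicates = 3, wt_per_run = 4,
               duration_h = 96, ...)
}
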
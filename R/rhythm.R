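#' @include AllClasses.R AllGenerics.R accessors.R
NULL

## pseudo-inverse fallback for near-singular J'J
.safe_inverse <- function(H) {
  out <- tryCatch(chol2inv(chol(H)), error = function(e) NULL)
  if (!is.null(out)) return(out)
  s <- svd(H)
  pos <- s$d > max(s$d) * 1e-12
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Periodogram-based seed components for cosine fitting
#'
#' The FFT half of FFT-NLLS: computes a discrete Fourier periodogram of the
#' (detrended) trace — zero-padded FFT for regularly sampled traces, a
#' least-squares periodogram on the same frequency grid otherwise — and
#' returns the top spectral peaks as initial cosine components, ordered by
#' power. Amplitude and phase of each candidate are obtained by ordinary
#' least squares of the trace on the cosine/sine pair at the peak frequency,
#' which is exact for irregular sampling too.
#'
#' @param trace a detrended [LuminescenceTrace-class] (>= 8 samples).
#' @param max_candidates maximum number of peaks to return.
#' @param min_power_frac candidates whose share of total periodogram power
#'   falls below this fraction are flagged \code{low_power = TRUE}.
#' @param pad_factor zero-padding factor of the FFT grid (frequency
#'   resolution is \code{1/(pad_factor * span)}).
#' @return data.frame with columns \code{period}, \code{amplitude},
#'   \code{phase}, \code{damping} (always 0 for seeds), \code{power_frac},
#'   \code{low_power}; zero rows for a signal-free trace.
#' @examples
#' t <- seq(0, 96, by = 0.5)
#' tr <- luminescenceTrace(times = t, values = cos(2 * pi * t / 22))
#' periodogramSeeds(tr)[1, "period"]
#' @export
periodogramSeeds <- function(trace, max_candidates = 4L,
                             min_power_frac = 0.05, pad_factor = 4L) {
  t <- trace@times
  y <- trace@values - mean(trace@values)
  n <- length(t)
  if (n < 8L) stop("periodogram seeding needs at least 8 samples")
  empty <- data.frame(period = numeric(), amplitude = numeric(),
                      phase = numeric(), damping = numeric(),
                      power_frac = numeric(), low_power = logical())
  if (all(abs(y) < 1e-12 * max(1, abs(mean(trace@values))))) return(empty)

  span <- max(t) - min(t)
  d <- diff(t)
  regular <- max(abs(d - d[1])) < 1e-8 * d[1]
  if (regular) {
    dt <- d[1]
    npad <- 2^ceiling(log2(pad_factor * n))
    X <- stats::fft(c(y, rep(0, npad - n)))
    freqs <- (seq_len(npad %/% 2) - 1) / (npad * dt)
    power <- Mod(X[seq_len(npad %/% 2)])^2
  } else {
    dt <- stats::median(d)
    freqs <- seq(0, 0.5 / dt, by = 1 / (pad_factor * span))
    power <- vapply(freqs, function(f) {
      if (f == 0) return(0)
      X <- cbind(cos(2 * pi * f * t), sin(2 * pi * f * t))
      sum(stats::lm.fit(X, y)$fitted.values^2)
    }, numeric(1))
  }
  usable <- freqs >= 1 / span & freqs > 0
  power[!usable] <- 0
  if (all(power == 0)) return(empty)

  # interior local maxima of the power spectrum, strongest first
  k <- length(power)
  is_peak <- c(FALSE, power[2:(k - 1)] > power[1:(k - 2)] &
                 power[2:(k - 1)] >= power[3:k], FALSE) & usable
  idx <- which(is_peak)
  if (!length(idx)) idx <- which.max(power)
  idx <- idx[order(power[idx], decreasing = TRUE)]
  idx <- idx[seq_len(min(length(idx), max_candidates))]

  total_power <- sum(power)
  seeds <- lapply(idx, function(i) {
    f <- freqs[i]
    X <- cbind(cos(2 * pi * f * t), sin(2 * pi * f * t))
    cf <- stats::lm.fit(X, y)$coefficients
    A <- sqrt(sum(cf^2))
    tau <- 1 / f
    phi <- (tau / (2 * pi)) * atan2(cf[2], cf[1])
    data.frame(period = tau, amplitude = A, phase = phi %% tau,
               damping = 0, power_frac = power[i] / total_power,
               low_power = power[i] / total_power < min_power_frac)
  })
  out <- do.call(rbind, seeds)
  rownames(out) <- NULL
  out
}

## pack/unpack NLLS parameters: (c, b, then per component a, b, tau [, lam])
.pars_per_comp <- function(damping) if (damping) 4L else 3L

.model_eval <- function(par, t, k, damping) {
  f <- par[1] + par[2] * t
  pc <- .pars_per_comp(damping)
  for (j in seq_len(k)) {
    o <- 2L + (j - 1L) * pc
    w <- 2 * pi / par[o + 3L]
    env <- if (damping) exp(-par[o + 4L] * t) else 1
    f <- f + (par[o + 1L] * cos(w * t) + par[o + 2L] * sin(w * t)) * env
  }
  f
}

.model_jac <- function(par, t, k, damping) {
  pc <- .pars_per_comp(damping)
  J <- matrix(0, length(t), 2L + k * pc)
  J[, 1] <- 1
  J[, 2] <- t
  for (j in seq_len(k)) {
    o <- 2L + (j - 1L) * pc
    tau <- par[o + 3L]
    w <- 2 * pi / tau
    cw <- cos(w * t); sw <- sin(w * t)
    env <- if (damping) exp(-par[o + 4L] * t) else rep(1, length(t))
    J[, o + 1L] <- cw * env
    J[, o + 2L] <- sw * env
    J[, o + 3L] <- (2 * pi * t / tau^2) *
      (par[o + 1L] * sw - par[o + 2L] * cw) * env
    if (damping)
      J[, o + 4L] <- -t * (par[o + 1L] * cw + par[o + 2L] * sw) * env
  }
  J
}

#' Fit a multi-component (damped) cosine model by nonlinear least squares
#'
#' The NLLS half of FFT-NLLS: starting from periodogram seed components,
#' minimises the sum of squared errors of
#' \deqn{y(t) = c + b t + \sum_k A_k e^{-\lambda_k t}
#'   \cos\{2\pi(t-\phi_k)/\tau_k\}}
#' by Levenberg-Marquardt (via \pkg{minpack.lm}), with each component
#' parameterised internally as an in-phase/quadrature pair for optimizer
#' stability. Component standard errors come from the local linearization
#' (covariance of the NLLS solution); amplitude SEs use the delta method.
#'
#' @param trace a detrended [LuminescenceTrace-class].
#' @param seeds seed components as returned by [periodogramSeeds()] (columns
#'   \code{period}, \code{amplitude}, \code{phase}; \code{damping}
#'   optional).
#' @param n_components number of components to fit (\code{0} reduces the
#'   fit to an ordinary least-squares line; must not exceed
#'   \code{nrow(seeds)}).
#' @param damping if TRUE each component carries its own exponential
#'   damping rate (>= 0); default off, which keeps the estimator
#'   identifiable on 4-5 day records.
#' @return a [DampedCosineModel-class]. The returned SSE never exceeds the
#'   SSE of the seed parameters; non-convergence is reported via the
#'   \code{converged} slot, never as an error.
#' @export
fitCosineModel <- function(trace, seeds, n_components = nrow(seeds),
                           damping = FALSE) {
  t <- trace@times
  y <- trace@values
  n <- length(t)
  k <- as.integer(n_components)
  if (k > 0 && (is.null(seeds) || nrow(seeds) < k))
    stop("n_components exceeds the number of seed components")

  if (k == 0L) {
    fit <- stats::lm.fit(cbind(1, t), y)
    cmp <- data.frame(amplitude = numeric(), period = numeric(),
                      phase = numeric(), damping = numeric(),
                      amplitude_se = numeric(), period_se = numeric())
    return(new("DampedCosineModel", intercept = unname(fit$coefficients[1]),
               slope = unname(fit$coefficients[2]), components = cmp,
               sse = sum(fit$residuals^2), nObs = n, converged = TRUE))
  }

  pc <- .pars_per_comp(damping)
  par0 <- numeric(2L + k * pc)
  line <- stats::lm.fit(cbind(1, t), y)$coefficients
  par0[1:2] <- line
  for (j in seq_len(k)) {
    o <- 2L + (j - 1L) * pc
    tau <- seeds$period[j]
    A <- seeds$amplitude[j]
    phi <- seeds$phase[j]
    par0[o + 1L] <- A * cos(2 * pi * phi / tau)
    par0[o + 2L] <- A * sin(2 * pi * phi / tau)
    par0[o + 3L] <- tau
    if (damping)
      par0[o + 4L] <- if ("damping" %in% names(seeds)) seeds$damping[j] else 0
  }
  lower <- rep(-Inf, length(par0))
  upper <- rep(Inf, length(par0))
  span <- max(t) - min(t)
  for (j in seq_len(k)) {
    o <- 2L + (j - 1L) * pc
    lower[o + 3L] <- 2 * min(diff(t))
    upper[o + 3L] <- 4 * span
    if (damping) { lower[o + 4L] <- 0; upper[o + 4L] <- 1 }
  }

  resid_fn <- function(p) y - .model_eval(p, t, k, damping)
  jac_fn <- function(p) -.model_jac(p, t, k, damping)
  # non-convergence is reported via the converged slot, not as a warning
  fit <- suppressWarnings(minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper, fn = resid_fn, jac = jac_fn,
    control = minpack.lm::nls.lm.control(maxiter = 200)))
  par <- fit$par
  sse <- sum(resid_fn(par)^2)
  sse0 <- sum(resid_fn(par0)^2)
  if (sse > sse0) { par <- par0; sse <- sse0 }  # optimization contract
  converged <- fit$info %in% 1:4

  p <- length(par)
  sigma2 <- if (n > p) sse / (n - p) else NA_real_
  cov <- if (!is.na(sigma2)) {
    J <- .model_jac(par, t, k, damping)
    .safe_inverse(crossprod(J)) * sigma2
  } else matrix(NA_real_, p, p)

  cmp <- do.call(rbind, lapply(seq_len(k), function(j) {
    o <- 2L + (j - 1L) * pc
    a <- par[o + 1L]; b <- par[o + 2L]; tau <- par[o + 3L]
    A <- sqrt(a^2 + b^2)
    phi <- if (A > 0) ((tau / (2 * pi)) * atan2(b, a)) %% tau else 0
    cab <- cov[c(o + 1L, o + 2L), c(o + 1L, o + 2L)]
    se_A <- if (A > 1e-12) {
      g <- c(a, b) / A
      sqrt(max(0, drop(t(g) %*% cab %*% g)))
    } else sqrt(max(diag(cab)))
    data.frame(amplitude = A, period = tau, phase = phi,
               damping = if (damping) par[o + 4L] else 0,
               amplitude_se = se_A,
               period_se = sqrt(max(0, cov[o + 3L, o + 3L])))
  }))
  cmp <- cmp[order(cmp$amplitude, decreasing = TRUE), , drop = FALSE]
  rownames(cmp) <- NULL
  new("DampedCosineModel", intercept = par[1], slope = par[2],
      components = cmp, sse = sse, nObs = n, converged = converged)
}

#' Classify the rhythmicity of a fitted trace
#'
#' A trace is \code{rhythmic} when its best in-window component has relative
#' amplitude error at or below the threshold; \code{low_signal} when its raw
#' mean signal is below \code{low_signal_fraction} of the plate's wild-type
#' median raw mean but the mean-normalized trace is rhythmic (faint
#' reporters rescued by normalization keep their period); otherwise
#' \code{arrhythmic}.
#'
#' @param rae relative amplitude error of the candidate component (NA if no
#'   fit / no in-window component).
#' @param period candidate period in hours (NA if none).
#' @param circadian_window numeric(2) period search window.
#' @param rae_threshold maximum RAE for a rhythmic call.
#' @param raw_mean mean raw signal of the trace (NA to skip the low-signal
#'   branch).
#' @param wt_raw_mean plate/run wild-type median raw mean signal.
#' @param low_signal_fraction low-signal cutoff as a fraction of
#'   \code{wt_raw_mean}.
#' @param normalized_rhythmic was the mean-normalized trace rhythmic?
#' @return one of \code{"rhythmic"}, \code{"low_signal"},
#'   \code{"arrhythmic"}.
#' @export
classifyRhythmicity <- function(rae, period, circadian_window = c(16, 32),
                                rae_threshold = 0.5, raw_mean = NA,
                                wt_raw_mean = NA,
                                low_signal_fraction = 0.1,
                                normalized_rhythmic = FALSE) {
  in_window <- !is.na(period) && period > circadian_window[1] &&
    period < circadian_window[2]
  if (in_window && !is.na(rae) && rae <= rae_threshold) return("rhythmic")
  if (!is.na(raw_mean) && !is.na(wt_raw_mean) &&
      raw_mean < low_signal_fraction * wt_raw_mean &&
      isTRUE(normalized_rhythmic)) return("low_signal")
  "arrhythmic"
}

#' Estimate the circadian period of a trace by FFT-NLLS
#'
#' Runs [periodogramSeeds()] and then incremental [fitCosineModel()]:
#' components are added in order of spectral power while every fitted
#' component's amplitude remains significantly nonzero (its ~95\%
#' confidence interval excludes 0), up to \code{max_components}. The
#' reported period is that of the largest-amplitude component whose period
#' lies inside the circadian search window; ties are broken by smaller RAE,
#' then smaller period. RAE is the half-width of the amplitude's ~95\%
#' confidence interval divided by the amplitude.
#'
#' @param x a preprocessed (trimmed, detrended) [LuminescenceTrace-class].
#' @param circadian_window numeric(2), period search window in hours.
#' @param rae_threshold maximum RAE for a rhythmic call.
#' @param max_components maximum number of cosine components.
#' @param damping fit per-component damping rates (default off).
#' @return a [PeriodEstimate-class]; traces with no significant in-window
#'   component are labelled arrhythmic with \code{period = NA}.
#' @examples
#' t <- seq(12, 108, by = 0.5)
#' tr <- luminescenceTrace(times = t, values = 50 * cos(2 * pi * t / 21.76))
#' period(estimatePeriod(detrendTrace(tr)))
#' @export
setMethod("estimatePeriod", "LuminescenceTrace",
          function(x, circadian_window = c(16, 32), rae_threshold = 0.5,
                   max_components = 4L, damping = FALSE) {
  if (circadian_window[1] >= circadian_window[2])
    stop("circadian_window must be (lo, hi) with lo < hi")
  mk_est <- function(period, period_se, amp, rae, label, fit, norm = FALSE)
    new("PeriodEstimate", period = period, periodSe = period_se,
        amplitude = amp, rae = rae, rhythmLabel = label,
        circadianWindow = as.numeric(circadian_window), fit = fit,
        runId = x@runId, plateId = x@plateId, well = x@well,
        strainId = x@strainId, genotypeClass = x@genotypeClass,
        reporterId = x@reporterId, rawMean = NA_real_, normalized = norm)

  seeds <- periodogramSeeds(x, max_candidates = max_components)
  if (nrow(seeds) == 0L)
    return(mk_est(NA_real_, NA_real_, NA_real_, NA_real_, "arrhythmic",
                  fitCosineModel(x, seeds, 0L)))

  model <- fitCosineModel(x, seeds, 0L)
  span <- max(x@times) - min(x@times)
  for (k in seq_len(min(nrow(seeds), max_components))) {
    cand <- fitCosineModel(x, seeds, k, damping = damping)
    # every fitted component must keep a significantly nonzero amplitude,
    # and no two components may come closer in frequency than half a
    # Fourier resolution element (1/span): closer pairs are unresolvable
    # and signal a degenerate fit (beating near-duplicates). Either
    # failure reverts to the previous model and stops the addition.
    cmp <- components(cand)
    half <- 1.96 * cmp$amplitude_se
    if (!all(is.finite(half)) || any(cmp$amplitude - half <= 0)) break
    if (k > 1L) {
      f <- sort(1 / cmp$period)
      if (min(diff(f)) < 0.5 / span) break
    }
    model <- cand
  }

  cmp <- components(model)
  inw <- which(cmp$period > circadian_window[1] &
                 cmp$period < circadian_window[2])
  if (!length(inw))
    return(mk_est(NA_real_, NA_real_, NA_real_, NA_real_, "arrhythmic",
                  model))
  cmp_rae <- 1.96 * cmp$amplitude_se[inw] / cmp$amplitude[inw]
  ord <- order(-cmp$amplitude[inw], cmp_rae, cmp$period[inw])
  best <- inw[ord[1]]
  rae <- 1.96 * cmp$amplitude_se[best] / cmp$amplitude[best]
  label <- classifyRhythmicity(rae, cmp$period[best], circadian_window,
                               rae_threshold)
  if (label == "arrhythmic")
    return(mk_est(NA_real_, NA_real_, cmp$amplitude[best], rae, label,
                  model))
  mk_est(cmp$period[best], cmp$period_se[best], cmp$amplitude[best], rae,
         label, model)
})
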
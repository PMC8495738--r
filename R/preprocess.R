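#' @include AllClasses.R AllGenerics.R accessors.R
NULL

.log_step <- function(trace, name, ...) {
  trace@processingLog <- c(trace@processingLog,
                           list(c(list(name = name), list(...))))
  trace
}

#' Trim the edges of a recording window
#'
#' Removes samples within \code{head_h} hours of the start and \code{tail_h}
#' hours of the end of a trace. The screens discard the first and last 12 h
#' of each recording to minimise noise from the light-to-dark transition and
#' to improve subsequent detrending; those are the defaults here.
#'
#' @param x a [LuminescenceTrace-class] or [TraceSet-class].
#' @param head_h,tail_h hours to remove from each end (>= 0).
#' @return the trimmed object; retained samples satisfy
#'   \code{time >= min(time) + head_h} and \code{time <= max(time) - tail_h}.
#' @examples
#' tr <- luminescenceTrace(times = 0:120, values = rep(1, 121))
#' range(times(trimWindow(tr)))  # 12 108
#' @export
setMethod("trimWindow", "LuminescenceTrace", function(x, head_h = 12,
                                                      tail_h = 12) {
  if (head_h < 0 || tail_h < 0) stop("trim amounts must be >= 0")
  dur <- max(x@times) - min(x@times)
  if (dur <= head_h + tail_h)
    stop(sprintf(
      "trace spans %.2f h but trimming %g + %g h requires more than %g h",
      dur, head_h, tail_h, head_h + tail_h))
  keep <- x@times >= min(x@times) + head_h & x@times <= max(x@times) - tail_h
  if (sum(keep) < 2L) stop("fewer than 2 samples would remain after trim")
  x@times <- x@times[keep]
  x@values <- x@values[keep]
  .log_step(x, "trim_window", head_h = head_h, tail_h = tail_h)
})

#' @rdname trimWindow
#' @export
setMethod("trimWindow", "TraceSet", function(x, head_h = 12, tail_h = 12)
  traceSet(lapply(x@traces, trimWindow, head_h = head_h, tail_h = tail_h)))

#' Detrend a trace by removing a least-squares polynomial trend
#'
#' Replaces the values by the residuals of an ordinary least-squares fit of
#' a linear (default) or low-order polynomial trend against time. Slow
#' trends in luminescence series (substrate depletion, signal decay) distort
#' period estimation; removing them is the first analysis step.
#'
#' @param x a [LuminescenceTrace-class] or [TraceSet-class].
#' @param method \code{"linear"} or \code{"polynomial"}.
#' @param order polynomial order (1-3; ignored for \code{method="linear"}).
#' @return the detrended object; residual mean is 0 up to numerical
#'   tolerance.
#' @export
setMethod("detrendTrace", "LuminescenceTrace",
          function(x, method = c("linear", "polynomial"), order = 1L) {
  method <- match.arg(method)
  if (method == "linear") order <- 1L
  order <- as.integer(order)
  if (order < 1L || order > 3L) stop("polynomial order must be 1-3")
  if (length(x@times) < order + 2L)
    stop(sprintf("detrending order %d needs at least %d samples", order,
                 order + 2L))
  # centred time improves conditioning for cubic trends on long records
  tc <- x@times - mean(x@times)
  X <- cbind(1, outer(tc, seq_len(order), `^`))
  fit <- stats::lm.fit(X, x@values)
  x@values <- unname(fit$residuals)
  .log_step(x, "detrend", method = method, order = order)
})

#' @rdname detrendTrace
#' @export
setMethod("detrendTrace", "TraceSet",
          function(x, method = c("linear", "polynomial"), order = 1L)
  traceSet(lapply(x@traces, detrendTrace, method = method, order = order)))

#' Normalize a trace to its mean
#'
#' Divides every value by the trace mean, so the output has mean 1. Applied
#' to raw (untrended) traces only: it rescales weak absolute signals onto a
#' relative scale, which is how faint-but-rhythmic reporters (a few percent
#' of wild-type signal) are rescued into the analysable range. Refuses
#' near-zero means — in particular already-detrended series — because the
#' division would blow up.
#'
#' @param x a [LuminescenceTrace-class] or [TraceSet-class].
#' @param epsilon near-zero guard: the mean must exceed \code{epsilon}
#'   times the value range.
#' @return the normalized object, mean 1 up to numerical tolerance.
#' @export
setMethod("normalizeToMean", "LuminescenceTrace",
          function(x, epsilon = 1e-6) {
  m <- mean(x@values)
  scale <- max(diff(range(x@values)), abs(m))
  if (scale == 0) scale <- 1
  if (abs(m) <= epsilon * scale)
    stop("cannot normalize: near-zero mean (is the trace already detrended?)")
  x@values <- x@values / m
  .log_step(x, "normalize_to_mean", mean = m)
})

#' @rdname normalizeToMean
#' @export
setMethod("normalizeToMean", "TraceSet", function(x, epsilon = 1e-6)
  traceSet(lapply(x@traces, normalizeToMean, epsilon = epsilon)))
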
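#' Uniformly sampled signal trace
#'
#' `sampled_trace` is the common carrier for every signal in the package:
#' speech, device-frame accelerations, surface EMG, and all derived series
#' (rotated accelerations, velocities, the ECMF). It couples a numeric
#' vector with its sampling rate, physical units and a start offset.
#'
#' @param samples Numeric vector of samples; all values must be finite.
#' @param rate Sampling rate in Hz (> 0).
#' @param units Free-text unit label (e.g. `"cm/s^2"`, `"mV"`, `"Hz"`,
#'   `"dimensionless"`).
#' @param label Channel name.
#' @param t0 Start time offset in seconds.
#' @return An object of class `sampled_trace`: a list with fields
#'   `samples`, `rate`, `units`, `label`, `t0`.
#' @examples
#' tr <- sampled_trace(sin(2 * pi * 5 * seq(0, 1, by = 1 / 500)), 500,
#'                     units = "cm/s^2", label = "a_y")
#' tr
#' @export
sampled_trace <- function(samples, rate, units = "dimensionless",
                          label = "signal", t0 = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L)
    stop("'samples' must contain at least one value", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("'samples' must be finite", call. = FALSE)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("'rate' must be a single positive number", call. = FALSE)
  structure(
    list(samples = samples, rate = as.numeric(rate),
         units = as.character(units), label = as.character(label),
         t0 = as.numeric(t0)),
    class = "sampled_trace"
  )
}

#' @export
print.sampled_trace <- function(x, ...) {
  dur <- (length(x$samples) - 1L) / x$rate
  cat(sprintf("<sampled_trace> '%s': %d samples @ %g Hz (%.3f s), units '%s'\n",
              x$label, length(x$samples), x$rate, dur, x$units))
  invisible(x)
}

#' @export
length.sampled_trace <- function(x) length(x$samples)

#' Time axis of a trace
#'
#' @param trace A [sampled_trace].
#' @return Numeric vector of sample times in seconds (`t0` onwards).
#' @export
trace_time <- function(trace) {
  stopifnot(inherits(trace, "sampled_trace"))
  trace$t0 + (seq_along(trace$samples) - 1L) / trace$rate
}

is_trace <- function(x) inherits(x, "sampled_trace")

assert_rate <- function(trace, rate, what = deparse(substitute(trace))) {
  if (abs(trace$rate - rate) > 1e-6)
    stop(sprintf("%s must be sampled at %g Hz (got %g Hz)", what, rate,
                 trace$rate), call. = FALSE)
  invisible(trace)
}
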
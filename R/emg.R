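#' Electromyographic correlate of the masseter force (ECMF)
#'
#' Computes the detrended time-integral of the rectified surface EMG:
#' `r_m(t) = integral |s_m|`, `f_m(t) = J_m r_m(t)`. The input must
#' already be low-passed to 250 Hz and downsampled to 500 Hz. A 20 Hz
#' high-pass precedes rectification to remove motion artifact (standard
#' sEMG practice; set `hp_cutoff = NULL` to disable). The cumulative
#' integral is high-pass detrended to suppress integration drift; with
#' `detrend_cutoff = NULL` the raw nondecreasing integral is returned.
#'
#' `J_m` lumps the unobserved torque and lever-arm constants into a single
#' proportionality and defaults to 1 (arbitrary units): the ECMF enters
#' the analysis only through correlations and regression slopes, which a
#' rescaling leaves untouched.
#'
#' @param semg_500 A [sampled_trace] at 500 Hz.
#' @param J_m Mioelectric proportionality constant.
#' @param detrend_cutoff Drift-removal high-pass cutoff in Hz, or `NULL`.
#' @param hp_cutoff Pre-rectification high-pass in Hz, or `NULL`.
#' @return Object of class `ecmf_series`: `t` (s), `r_m`, `f_m` (a.u.),
#'   `J_m`, `rate`.
#' @export
ecmf <- function(semg_500, J_m = 1, detrend_cutoff = 0.5, hp_cutoff = 20) {
  stopifnot(is_trace(semg_500))
  assert_rate(semg_500, 500, "semg")
  fs <- semg_500$rate
  s <- semg_500$samples
  if (!is.null(hp_cutoff) && hp_cutoff > 0) {
    bf <- signal::butter(2, hp_cutoff / (fs / 2), type = "high")
    s <- zero_phase(s, bf, ceiling(2 * fs / hp_cutoff))
  }
  r <- cumtrapz_uniform(abs(s), 1 / fs)
  if (!is.null(detrend_cutoff))
    r <- detrend(r, detrend_cutoff, rate = fs)
  structure(
    list(t = trace_time(semg_500), r_m = r, f_m = J_m * r, J_m = J_m,
         rate = fs),
    class = "ecmf_series"
  )
}

#' @export
print.ecmf_series <- function(x, ...) {
  cat(sprintf("<ecmf_series> %d samples @ %g Hz, J_m = %g\n",
              length(x$t), x$rate, x$J_m))
  invisible(x)
}
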
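# Zero-phase filtering with odd-reflection padding. Forward-backward
# application of a Butterworth section doubles the effective order and
# cancels group delay, so cross-modal lag estimates are not corrupted by
# the anti-alias / detrend stages.

zero_phase <- function(x, filt, pad) {
  n <- length(x)
  p <- min(n - 1L, as.integer(pad))
  if (p > 0L) {
    head_pad <- 2 * x[1L] - x[(p + 1L):2L]
    tail_pad <- 2 * x[n] - x[(n - 1L):(n - p)]
    xp <- c(head_pad, x, tail_pad)
  } else {
    xp <- x
  }
  y <- signal::filter(filt, xp)
  y <- rev(signal::filter(filt, rev(y)))
  if (p > 0L) y <- y[(p + 1L):(p + n)]
  as.numeric(y)
}

# Zero-phase filtering with the endpoint-connecting line removed first, so
# the odd-reflection padding is continuous and step-free at both edges (a
# signal ending off-zero otherwise injects a 2*x[n] step whose high-pass
# transient bleeds seconds into the interior at sub-Hz cutoffs). The line
# is restored for low-pass filters (it lies in their passband) and dropped
# for high-pass filters (it is trend).
zero_phase_detr <- function(x, filt, pad, restore_line) {
  n <- length(x)
  if (n < 2L) return(x * 0)
  line <- x[1L] + (x[n] - x[1L]) * (seq_len(n) - 1) / (n - 1)
  y <- zero_phase(x - line, filt, pad)
  if (restore_line) y + line else y
}

#' Anti-alias low-pass filtering and downsampling
#'
#' Low-pass filters a trace with a zero-phase (forward-backward)
#' Butterworth filter and resamples it onto a coarser uniform grid. This is
#' the standard pre-processing applied to every channel: speech is filtered
#' to 4 kHz and taken to 8 kHz, acceleration and sEMG are filtered to
#' 250 Hz and taken to 500 Hz.
#'
#' Upsampling is not supported: `target_rate` must not exceed the input
#' rate, and `cutoff` must respect the output Nyquist frequency.
#'
#' @param trace A [sampled_trace].
#' @param target_rate Output sampling rate in Hz.
#' @param cutoff Low-pass cutoff in Hz; defaults to `target_rate / 2`.
#' @param order Butterworth order of a single pass (applied twice).
#' @return A [sampled_trace] at `target_rate`, same units and label.
#' @export
resample_antialias <- function(trace, target_rate, cutoff = target_rate / 2,
                               order = 8) {
  stopifnot(is_trace(trace))
  if (target_rate > trace$rate + 1e-9)
    stop("upsampling is not supported (target_rate > rate)", call. = FALSE)
  if (cutoff > target_rate / 2 + 1e-9)
    stop("'cutoff' must be <= target_rate / 2", call. = FALSE)
  x <- trace$samples
  if (abs(target_rate - trace$rate) < 1e-9 && cutoff >= trace$rate / 2 - 1e-9)
    return(trace)
  w <- cutoff / (trace$rate / 2)
  if (w < 1) {
    bf <- signal::butter(order, w, type = "low")
    pad <- ceiling(4 * trace$rate / cutoff)
    x <- zero_phase_detr(x, bf, pad, restore_line = TRUE)
  }
  t_in <- trace$t0 + (seq_along(x) - 1L) / trace$rate
  dur <- (length(x) - 1L) / trace$rate
  n_out <- floor(dur * target_rate) + 1L
  t_out <- trace$t0 + (seq_len(n_out) - 1L) / target_rate
  y <- stats::approx(t_in, x, xout = t_out)$y
  sampled_trace(y, target_rate, units = trace$units, label = trace$label,
                t0 = trace$t0)
}

#' High-pass detrending
#'
#' Removes slow drift (including the mean and any linear trend) by
#' subtracting a Gaussian local-mean trend estimate. The kernel width is
#' matched to the requested cutoff (`sigma = sqrt(2 log 2) / (2 pi
#' cutoff_hz)`, the -3 dB point), and at the edges the truncated kernel is
#' renormalized rather than reflected, so the operation is zero-phase and
#' free of the long startup transients an IIR high-pass would smear into
#' the signal — which matters because detrending runs after every
#' integration stage, where low-frequency artifacts are amplified.
#'
#' The Gaussian response leaves components well above the cutoff untouched
#' (the trend estimate retains less than 1e-6 of any component at five
#' times the cutoff) and removes DC exactly.
#'
#' @param trace A [sampled_trace], or a bare numeric vector together with
#'   `rate`.
#' @param cutoff_hz High-pass cutoff in Hz (default 0.5); must satisfy
#'   `0 < cutoff_hz < rate / 2`.
#' @param rate Sampling rate, only when `trace` is a bare numeric vector.
#' @return Same type as the input (trace in, trace out).
#' @export
detrend <- function(trace, cutoff_hz = 0.5, rate = NULL) {
  bare <- !is_trace(trace)
  if (bare) {
    if (is.null(rate)) stop("'rate' required for bare numeric input",
                            call. = FALSE)
    trace <- sampled_trace(trace, rate)
  }
  if (cutoff_hz <= 0 || cutoff_hz >= trace$rate / 2)
    stop("'cutoff_hz' must be in (0, rate/2)", call. = FALSE)
  x <- trace$samples
  sigma <- sqrt(2 * log(2)) / (2 * pi * cutoff_hz) * trace$rate  # samples
  # the endpoint-connecting line is removed first so that steep ramps
  # (e.g. cumulative integrals before drift removal) are not biased by the
  # asymmetric truncated kernel near the edges
  n <- length(x)
  line <- if (n > 1L)
    x[1L] + (x[n] - x[1L]) * (seq_len(n) - 1) / (n - 1) else x
  r <- x - line
  y <- r - gaussian_trend(r, sigma)
  if (bare) return(y)
  sampled_trace(y, trace$rate, units = trace$units, label = trace$label,
                t0 = trace$t0)
}

# Gaussian-kernel local mean with edge renormalization (truncated kernel
# re-scaled to unit mass), computed by direct convolution.
gaussian_trend <- function(x, sigma) {
  n <- length(x)
  half <- min(n - 1L, ceiling(4 * sigma))
  k <- exp(-0.5 * ((-half):half / sigma)^2)
  num <- stats::filter(c(rep(0, half), x, rep(0, half)), k, sides = 2)
  den <- stats::filter(c(rep(0, half), rep(1, n), rep(0, half)), k,
                       sides = 2)
  idx <- (half + 1L):(half + n)
  as.numeric(num[idx] / den[idx])
}

#' Zero-phase low-pass filtering
#'
#' Forward-backward Butterworth low-pass on a bare numeric vector, used
#' throughout the package to band-limit series before numerical
#' differentiation. Zero phase, so it never shifts cross-modal lags.
#'
#' @param x Numeric vector.
#' @param rate Sampling rate, Hz.
#' @param cutoff Low-pass cutoff, Hz; a cutoff at or above the Nyquist
#'   frequency returns the input unchanged.
#' @param order Butterworth order of a single pass (applied twice).
#' @return Filtered numeric vector of the same length.
#' @export
lowpass <- function(x, rate, cutoff, order = 4) {
  if (cutoff >= rate / 2) return(x)
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  zero_phase_detr(x, bf, ceiling(4 * rate / cutoff), restore_line = TRUE)
}

# Cumulative trapezoidal integral on a uniform grid.
cumtrapz_uniform <- function(x, dt) {
  n <- length(x)
  if (n < 2L) return(numeric(n))
  c(0, cumsum((x[-1L] + x[-n]) / 2) * dt)
}

# Zero-phase Hann-window moving average (edge-renormalized); matches the
# smearing of framewise short-time analysis with the same window length.
hann_smooth <- function(x, rate, window_ms) {
  m <- max(3L, round(window_ms / 1000 * rate))
  if (m %% 2L == 0L) m <- m + 1L
  k <- 0.5 - 0.5 * cos(2 * pi * (seq_len(m) - 1) / (m - 1))
  half <- (m - 1L) %/% 2L
  num <- stats::filter(c(rep(0, half), x, rep(0, half)), k, sides = 2)
  den <- stats::filter(c(rep(0, half), rep(1, length(x)), rep(0, half)), k,
                       sides = 2)
  idx <- (half + 1L):(half + length(x))
  as.numeric(num[idx] / den[idx])
}

# Dominant frequency (Hz) of a series by periodogram peak in (0.3, 10] Hz.
dominant_freq <- function(x, rate) {
  n <- length(x)
  sp <- Mod(stats::fft(x - mean(x)))[1:(n %/% 2)]^2
  fr <- (seq_len(n %/% 2) - 1) * rate / n
  band <- fr > 0.3 & fr <= 10
  if (!any(band)) return(2.5)
  fr[band][which.max(sp[band])]
}
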
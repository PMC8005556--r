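#' Estimate the accelerometer mounting angle
#'
#' The gravity direction defines the vertical: per short window, the angle
#' is `theta = atan2(mean(accel_x), mean(accel_y))` of the window-mean
#' device-frame acceleration, then linearly interpolated to a per-sample
#' angle. Dynamic (zero-mean) components average out over the windows.
#'
#' @param accel_x,accel_y Device-frame [sampled_trace]s at a common rate
#'   and span.
#' @param window_s Window length in seconds (50% overlap).
#' @return Object of class `rotation_estimate`: `window_centers` (s),
#'   `theta` (rad per window), `theta_interp` (rad per sample), `rate`.
#' @export
estimate_rotation <- function(accel_x, accel_y, window_s = 0.5) {
  stopifnot(is_trace(accel_x), is_trace(accel_y),
            abs(accel_x$rate - accel_y$rate) < 1e-9,
            length(accel_x$samples) == length(accel_y$samples))
  fs <- accel_x$rate
  n <- length(accel_x$samples)
  w <- max(2L, round(window_s * fs))
  hop <- max(1L, w %/% 2L)
  starts <- seq(1L, max(1L, n - w + 1L), by = hop)
  mx <- vapply(starts, function(s) mean(accel_x$samples[s:min(s + w - 1L, n)]),
               numeric(1))
  my <- vapply(starts, function(s) mean(accel_y$samples[s:min(s + w - 1L, n)]),
               numeric(1))
  mag <- sqrt(mx^2 + my^2)
  if (any(mag < 1e-6))
    stop("rotation undefined: near-zero mean acceleration vector",
         call. = FALSE)
  theta <- atan2(mx, my)
  centers <- accel_x$t0 + (starts - 1L + (w - 1L) / 2) / fs
  t_all <- trace_time(accel_x)
  theta_interp <- if (length(theta) == 1L) rep(theta, n) else
    stats::approx(centers, theta, xout = t_all, rule = 2)$y
  structure(list(window_centers = centers, theta = theta,
                 theta_interp = theta_interp, rate = fs),
            class = "rotation_estimate")
}

#' @export
print.rotation_estimate <- function(x, ...) {
  cat(sprintf("<rotation_estimate> %d windows, mean theta = %.4f rad (%.2f deg)\n",
              length(x$theta), mean(x$theta), mean(x$theta) * 180 / pi))
  invisible(x)
}

#' Rotate device-frame accelerations into the sagittal frame
#'
#' Inverts the mounting rotation per sample:
#' `a_ref = t(R(theta)) %*% a_device` with
#' `R(theta) = rbind(c(cos, sin), c(-sin, cos))`. After rotation the +y
#' axis is anti-gravity, so gravity appears as a DC offset on `a_yd` that
#' downstream detrending removes. The rotation is an isometry: the
#' per-sample norm is preserved.
#'
#' @param accel_x,accel_y Device-frame [sampled_trace]s.
#' @param rotation A `rotation_estimate` (or a single angle in rad).
#' @return List of [sampled_trace]s `a_xd`, `a_yd` (sagittal frame).
#' @export
rotate_accel <- function(accel_x, accel_y, rotation) {
  theta <- if (inherits(rotation, "rotation_estimate"))
    rotation$theta_interp else rep(as.numeric(rotation),
                                   length(accel_x$samples))
  ct <- cos(theta); st <- sin(theta)
  axd <- ct * accel_x$samples - st * accel_y$samples
  ayd <- st * accel_x$samples + ct * accel_y$samples
  list(
    a_xd = sampled_trace(axd, accel_x$rate, units = accel_x$units,
                         label = "a_xd", t0 = accel_x$t0),
    a_yd = sampled_trace(ayd, accel_y$rate, units = accel_y$units,
                         label = "a_yd", t0 = accel_y$t0)
  )
}

#' Integrate sagittal accelerations to a velocity series
#'
#' Cumulative trapezoidal integration of each component followed by
#' high-pass detrending (integration-drift removal), and the absolute
#' kinematic velocity `speed = sqrt(vx^2 + vy^2)`.
#'
#' @param a_xd,a_yd Detrended sagittal-frame [sampled_trace]s (cm/s^2).
#' @param detrend_cutoff Drift-removal high-pass cutoff, Hz.
#' @return Object of class `velocity_series`: `t` (s), `vx`, `vy`,
#'   `speed` (cm/s), `rate`.
#' @export
integrate_velocity <- function(a_xd, a_yd, detrend_cutoff = 0.5) {
  stopifnot(is_trace(a_xd), is_trace(a_yd))
  if (!all(is.finite(a_xd$samples)) || !all(is.finite(a_yd$samples)))
    stop("non-finite acceleration input", call. = FALSE)
  fs <- a_xd$rate
  dt <- 1 / fs
  vx <- detrend(cumtrapz_uniform(a_xd$samples, dt), detrend_cutoff,
                rate = fs)
  vy <- detrend(cumtrapz_uniform(a_yd$samples, dt), detrend_cutoff,
                rate = fs)
  structure(
    list(t = trace_time(a_xd), vx = vx, vy = vy,
         speed = sqrt(vx^2 + vy^2), rate = fs),
    class = "velocity_series"
  )
}

#' @export
print.velocity_series <- function(x, ...) {
  cat(sprintf("<velocity_series> %d samples @ %g Hz, peak speed %.3g cm/s\n",
              length(x$t), x$rate, max(x$speed)))
  invisible(x)
}

#' Quadratic coefficients of the absolute formant velocity form
#'
#' Expands `|W %*% dFdt|^2` into the quadratic form
#' `H1 (dF1/dt)^2 + H2 (dF2/dt)^2 + H12 (dF1/dt)(dF2/dt)` with
#' `H1 = w11^2 + w21^2`, `H2 = w12^2 + w22^2`,
#' `H12 = 2 (w11 w12 + w21 w22)`. The form is positive semidefinite
#' (`H12^2 <= 4 H1 H2`) by construction.
#'
#' @param W 2x2 inverse projection matrix (cm/Hz).
#' @return List with `H1`, `H2`, `H12`.
#' @export
quad_coeffs <- function(W) {
  stopifnot(is.matrix(W), all(dim(W) == 2), all(is.finite(W)))
  list(H1 = W[1, 1]^2 + W[2, 1]^2,
       H2 = W[1, 2]^2 + W[2, 2]^2,
       H12 = 2 * (W[1, 1] * W[1, 2] + W[2, 1] * W[2, 2]))
}

#' Absolute formant velocity
#'
#' Evaluates `|v_f(t)| = sqrt(H1 dF1^2 + H2 dF2^2 + H12 dF1 dF2)` on the
#' formant-track grid. `H` must be positive semidefinite; tiny negative
#' radicands (roundoff) are clamped to zero.
#'
#' @param dF1,dF2 Formant derivatives, Hz/s.
#' @param H Coefficients from [quad_coeffs()].
#' @return Nonnegative numeric vector, cm/s.
#' @export
afv <- function(dF1, dF2, H) {
  if (H$H1 < 0 || H$H2 < 0 || H$H12^2 > 4 * H$H1 * H$H2 * (1 + 1e-9))
    stop("'H' must define a positive semidefinite form", call. = FALSE)
  rad <- H$H1 * dF1^2 + H$H2 * dF2^2 + H$H12 * dF1 * dF2
  if (any(rad < -1e-9))
    stop("negative radicand: indefinite coefficients", call. = FALSE)
  sqrt(pmax(rad, 0))
}
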
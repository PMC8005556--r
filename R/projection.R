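#' Optimal time-lag alignment by cross-correlation
#'
#' Searches a grid of integer sample lags for the one maximizing the
#' absolute Pearson correlation between two series on a common rate (both
#' mean-removed by the correlation itself). Ties are broken toward the
#' smallest absolute lag. A positive lag means the second series is
#' delayed relative to the first: the optimum pairs `x[i]` with
#' `y[i + lag]`.
#'
#' @param x,y [sampled_trace]s at a common rate, or numeric vectors with
#'   `rate` supplied.
#' @param max_lag_ms Half-width of the lag search grid, ms.
#' @param rate Sampling rate when `x`, `y` are bare vectors.
#' @param min_overlap_s Minimum overlap after shifting, seconds.
#' @return Object of class `alignment_result`: `lag` (samples, signed),
#'   `lag_ms`, `r_pearson`, `r_spearman` (both at the optimal lag),
#'   `n_overlap`.
#' @export
xcorr_align <- function(x, y, max_lag_ms = 100, rate = NULL,
                        min_overlap_s = 2) {
  if (is_trace(x)) { rate <- x$rate; x <- x$samples }
  if (is_trace(y)) {
    if (abs(y$rate - rate) > 1e-6)
      stop("'x' and 'y' must share a sampling rate", call. = FALSE)
    y <- y$samples
  }
  if (is.null(rate)) stop("'rate' required for bare vectors", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant series", call. = FALSE)
  max_lag <- floor(max_lag_ms / 1000 * rate)
  n <- min(length(x), length(y))
  min_overlap <- max(3L, ceiling(min_overlap_s * rate))
  if (n - max_lag < min_overlap)
    stop("insufficient overlap after shifting", call. = FALSE)

  lags <- -max_lag:max_lag
  lags <- lags[order(abs(lags), lags)]       # smallest |lag| first
  r_of <- function(lag) {
    if (lag >= 0) {
      xi <- x[1:(n - lag)]; yi <- y[(1 + lag):n]
    } else {
      xi <- x[(1 - lag):n]; yi <- y[1:(n + lag)]
    }
    suppressWarnings(stats::cor(xi, yi))
  }
  rs <- vapply(lags, r_of, numeric(1))
  rs[!is.finite(rs)] <- 0
  # ties (within numerical tolerance) resolve to the smallest |lag|
  pick <- which(abs(rs) >= max(abs(rs)) - 1e-12)[1L]
  best <- list(lag = lags[pick], r = rs[pick])
  lag <- best$lag
  if (lag >= 0) {
    xi <- x[1:(n - lag)]; yi <- y[(1 + lag):n]
  } else {
    xi <- x[(1 - lag):n]; yi <- y[1:(n + lag)]
  }
  structure(
    list(lag = lag, lag_ms = 1000 * lag / rate, r_pearson = best$r,
         r_spearman = suppressWarnings(
           stats::cor(xi, yi, method = "spearman")),
         n_overlap = length(xi), rate = rate),
    class = "alignment_result"
  )
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> lag = %d samples (%.1f ms), r = %.3f (n = %d)\n",
              x$lag, x$lag_ms, x$r_pearson, x$n_overlap))
  invisible(x)
}

trim_burn_in <- function(v, rate, burn_in_s) {
  k <- round(burn_in_s * rate)
  n <- length(v)
  if (2 * k >= n - 2) return(v)
  v[(k + 1):(n - k)]
}

#' Fit the articulatory-to-acoustic projection model
#'
#' The core estimator of the package. Regresses unbiased formant
#' oscillations on the vertical jaw-tongue displacement after optimal
#' cross-correlation lag alignment, one ordinary-least-squares fit per
#' formant:
#' `delta_F1 = a21 dy`, `delta_F2 = a22 dy` (gains in Hz/cm internally,
#' reported in the tabulated "x 10^3" Hz/m convention). The inverse map
#' `W = solve(A)` and the quadratic coefficients `H` of the absolute
#' formant velocity are derived from the fitted matrix.
#'
#' When only the vertical displacement is available (the usual case), the
#' 2x2 matrix is completed with a synthetic-convention horizontal column
#' equal to 20% of the magnitude of the fitted vertical gains, positive
#' sign, and the result is flagged `vertical_only`. When a horizontal
#' displacement `dx` is supplied, both columns are fitted jointly and
#' `W %*% A` equals the identity to machine precision.
#'
#' The first and last `burn_in_s` seconds are excluded from alignment and
#' regression (filter edge transients).
#'
#' @param dy Vertical displacement, cm: a [sampled_trace] (500 Hz grid) or
#'   numeric vector with `rate`.
#' @param track A `formant_track` (run through [unbias()]; done here if
#'   missing), or supply `dF1`/`dF2` directly.
#' @param dF1,dF2 Unbiased formant oscillations (Hz) on the `dy` grid,
#'   alternatives to `track`.
#' @param dx Optional horizontal displacement (cm) for the full 2x2 fit.
#' @param rate Sampling rate of bare-vector inputs, Hz.
#' @param max_lag_ms Lag search half-width, ms.
#' @param burn_in_s Edge exclusion, seconds.
#' @param deriv_cutoff Zero-phase low-pass (Hz) applied to both series
#'   before alignment and regression, so that only the band where the
#'   articulatory signal dominates enters the fit. The default `"auto"`
#'   uses three times the dominant frequency of `dy` (clamped to
#'   \[4, 15\] Hz), covering the syllable fundamental and its first
#'   harmonics. A number fixes the cutoff; `NULL` disables.
#' @param track_window_ms Length of the formant analysis window, ms. The
#'   displacement is convolved with a Hann window of this length before
#'   regression so that both series share the smearing the framewise
#'   spectral analysis imposes on the formant tracks; without it the
#'   fitted gains are biased low by the window's passband droop. `NULL`
#'   disables.
#' @return Object of class `projection_model`; see Details. Key fields:
#'   `table` (a21, a22 in the x 10^3 Hz/m convention), `gains_hz_cm`,
#'   `r21`, `r22`, `lags_ms`, `A`, `W`, `H`, `fits` (the two `lm` fits),
#'   `vertical_only`.
#' @examples
#' sc <- articulation_scenario(duration = 4, noise_accel = 0, seed = 2)
#' rec <- make_recording(sc)
#' an <- analyze_recording(rec)
#' an$projection
#' coef(an$projection)
#' @export
fit_projection <- function(dy, track = NULL, dF1 = NULL, dF2 = NULL,
                           dx = NULL, rate = NULL, max_lag_ms = 100,
                           burn_in_s = 0.25, deriv_cutoff = "auto",
                           track_window_ms = 64) {
  if (is_trace(dy)) { rate <- dy$rate; t_dy <- trace_time(dy); dy <- dy$samples }
  else {
    if (is.null(rate)) stop("'rate' required", call. = FALSE)
    t_dy <- (seq_along(dy) - 1L) / rate
  }
  if (!is.null(track)) {
    if (is.null(track$delta1)) track <- unbias(track)
    dF1 <- stats::approx(track$times, track$delta1, xout = t_dy,
                         rule = 2)$y
    dF2 <- stats::approx(track$times, track$delta2, xout = t_dy,
                         rule = 2)$y
  }
  if (is.null(dF1) || is.null(dF2))
    stop("supply either 'track' or both 'dF1' and 'dF2'", call. = FALSE)
  if (!is.null(track_window_ms)) {
    dy <- hann_smooth(dy, rate, track_window_ms)
    if (!is.null(dx)) dx <- hann_smooth(dx, rate, track_window_ms)
  }
  if (identical(deriv_cutoff, "auto"))
    deriv_cutoff <- min(15, max(4, 3 * dominant_freq(dy, rate)))
  if (!is.null(deriv_cutoff)) {
    dy <- lowpass(dy, rate, deriv_cutoff)
    dF1 <- lowpass(dF1, rate, deriv_cutoff)
    dF2 <- lowpass(dF2, rate, deriv_cutoff)
  }

  dy_t <- trim_burn_in(dy, rate, burn_in_s)
  if (length(dy_t) < 2 * rate)
    stop("insufficient data: need at least 2 s after burn-in",
         call. = FALSE)
  dx_t <- if (!is.null(dx)) trim_burn_in(dx, rate, burn_in_s) else NULL

  fit_one <- function(dF) {
    dF_t <- trim_burn_in(dF, rate, burn_in_s)
    al <- xcorr_align(dy_t, dF_t, max_lag_ms = max_lag_ms, rate = rate)
    lag <- al$lag
    n <- min(length(dy_t), length(dF_t))
    if (lag >= 0) { ix <- 1:(n - lag); iy <- (1 + lag):n }
    else { ix <- (1 - lag):n; iy <- 1:(n + lag) }
    dat <- data.frame(dy = dy_t[ix], dF = dF_t[iy])
    if (!is.null(dx_t)) dat$dx <- dx_t[ix]
    fml <- if (is.null(dx_t)) dF ~ dy else dF ~ dx + dy
    fit <- stats::lm(fml, data = dat)
    list(align = al, fit = fit)
  }
  f1 <- fit_one(dF1)
  f2 <- fit_one(dF2)
  g1 <- unname(stats::coef(f1$fit)["dy"])   # Hz/cm
  g2 <- unname(stats::coef(f2$fit)["dy"])

  if (!is.null(dx_t)) {
    A <- matrix(c(unname(stats::coef(f1$fit)["dx"]),
                  unname(stats::coef(f2$fit)["dx"]), g1, g2), 2, 2)
    vertical_only <- FALSE
  } else {
    A <- matrix(c(0.2 * abs(g1), 0.2 * abs(g2), g1, g2), 2, 2)
    vertical_only <- TRUE
  }
  W <- solve(A)
  structure(
    list(
      table = c(a21 = g1 / 10, a22 = g2 / 10),  # x 10^3, Hz/m convention
      gains_hz_cm = c(f1 = g1, f2 = g2),
      r21 = f1$align$r_pearson, r22 = f2$align$r_pearson,
      spearman = c(r21 = f1$align$r_spearman, r22 = f2$align$r_spearman),
      lags_ms = c(f1 = f1$align$lag_ms, f2 = f2$align$lag_ms),
      # per-formant lags carry equal and opposite quadrature bias from any
      # horizontal-motion cross-talk (the horizontal column is
      # proportional to the vertical one), so their mean estimates the
      # common neuromotor-to-acoustic latency
      lag_consensus_ms = (f1$align$lag_ms + f2$align$lag_ms) / 2,
      A = A, W = W, H = quad_coeffs(W),
      fits = list(f1 = f1$fit, f2 = f2$fit),
      vertical_only = vertical_only, rate = rate,
      n = stats::nobs(f1$fit)
    ),
    class = "projection_model"
  )
}

#' @export
print.projection_model <- function(x, ...) {
  cat("Articulatory-to-acoustic projection model",
      if (x$vertical_only) "(vertical displacement only)" else
        "(full 2x2 fit)", "\n")
  cat(sprintf("  a21 = %.4g, a22 = %.4g  (x 10^3; Hz/m)\n",
              x$table["a21"], x$table["a22"]))
  cat(sprintf("  r21 = %.3f, r22 = %.3f; lags = %.1f, %.1f ms; n = %d\n",
              x$r21, x$r22, x$lags_ms[1], x$lags_ms[2], x$n))
  invisible(x)
}

#' @export
coef.projection_model <- function(object, ...) object$table

#' @export
summary.projection_model <- function(object, ...) {
  structure(list(model = object,
                 s1 = summary(object$fits$f1),
                 s2 = summary(object$fits$f2)),
            class = "summary.projection_model")
}

#' @export
print.summary.projection_model <- function(x, ...) {
  print(x$model)
  cat("\nFormant 1 regression (delta_F1 ~ dy):\n")
  stats::printCoefmat(x$s1$coefficients)
  cat("\nFormant 2 regression (delta_F2 ~ dy):\n")
  stats::printCoefmat(x$s2$coefficients)
  cat(sprintf("\nInverse map W (cm/Hz), H1 = %.3e, H2 = %.3e, H12 = %.3e\n",
              x$model$H$H1, x$model$H$H2, x$model$H$H12))
  invisible(x)
}

#' Predict formant oscillations from displacement
#'
#' @param object A `projection_model`.
#' @param newdata Data frame with column `dy` (cm) and optionally `dx`.
#' @param ... Unused.
#' @return Data frame with `dF1`, `dF2` (Hz).
#' @export
predict.projection_model <- function(object, newdata, ...) {
  dx <- if ("dx" %in% names(newdata)) newdata$dx else 0
  dF <- object$A %*% rbind(dx, newdata$dy)
  data.frame(dF1 = dF[1, ], dF2 = dF[2, ])
}

#' @export
residuals.projection_model <- function(object, ...) {
  list(f1 = stats::residuals(object$fits$f1),
       f2 = stats::residuals(object$fits$f2))
}

#' @export
plot.projection_model <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  for (i in 1:2) {
    fit <- x$fits[[i]]
    graphics::plot(fit$model$dy, fit$model$dF, pch = ".",
                   xlab = "dy (cm)",
                   ylab = sprintf("delta_F%d (Hz)", i),
                   main = sprintf("r = %.2f", if (i == 1) x$r21 else x$r22))
    graphics::abline(fit, col = 2, lwd = 2)
  }
  invisible(x)
}

#' Fit an aligned pairwise regression
#'
#' Aligns two series at the optimal cross-correlation lag and fits
#' `y = slope * x + intercept` by ordinary least squares. Used for the
#' three standard pairings: (ECMF, dynamic vertical acceleration),
#' (ECMF, acoustic vertical acceleration), and (dynamic, acoustic).
#'
#' @param x,y [sampled_trace]s on a common 500 Hz grid (or vectors with
#'   `rate`).
#' @param max_lag_ms Lag search half-width, ms.
#' @param rate Rate for bare vectors.
#' @param burn_in_s Edge exclusion, seconds.
#' @return Object of class `pairwise_fit`: `slope`, `intercept`,
#'   `r_pearson`, `r_spearman`, `lag` (samples), `lag_ms`, `n_overlap`.
#' @export
fit_pairwise <- function(x, y, max_lag_ms = 100, rate = NULL,
                         burn_in_s = 0.25) {
  if (is_trace(x)) { rate <- x$rate; x <- x$samples }
  if (is_trace(y)) y <- y$samples
  if (is.null(rate)) stop("'rate' required", call. = FALSE)
  x <- trim_burn_in(x, rate, burn_in_s)
  y <- trim_burn_in(y, rate, burn_in_s)
  al <- xcorr_align(x, y, max_lag_ms = max_lag_ms, rate = rate)
  lag <- al$lag
  n <- min(length(x), length(y))
  if (lag >= 0) { xi <- x[1:(n - lag)]; yi <- y[(1 + lag):n] }
  else { xi <- x[(1 - lag):n]; yi <- y[1:(n + lag)] }
  fit <- stats::lm(yi ~ xi)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_pearson = al$r_pearson, r_spearman = al$r_spearman,
         lag = al$lag, lag_ms = al$lag_ms, n_overlap = al$n_overlap),
    class = "pairwise_fit"
  )
}

#' @export
print.pairwise_fit <- function(x, ...) {
  cat(sprintf("<pairwise_fit> slope = %.4g, r = %.3f, lag = %d samples (%.1f ms)\n",
              x$slope, x$r_pearson, x$lag, x$lag_ms))
  invisible(x)
}

#' Acoustic acceleration correlates from formant tracks
#'
#' Projects the unbiased formant oscillations back through the inverse map
#' `W` to displacement correlates `(dx_hat, dy_hat) = W %*% (dF1, dF2)`,
#' interpolates onto a 500 Hz grid, and differentiates twice (central
#' differences with detrending after each stage, preceded by a zero-phase
#' low-pass in the articulatory band).
#'
#' @param track A `formant_track` processed by [unbias()] (done here if
#'   needed).
#' @param W 2x2 inverse projection matrix, cm/Hz.
#' @param rate_out Output grid rate, Hz.
#' @param deriv_cutoff Low-pass cutoff before differentiation, Hz.
#' @param detrend_cutoff Detrend cutoff between stages, Hz.
#' @return List of [sampled_trace]s `a_fx`, `a_fy` (cm/s^2) plus the
#'   displacement correlates `dx_hat`, `dy_hat`.
#' @export
acoustic_accel <- function(track, W, rate_out = 500, deriv_cutoff = 15,
                           detrend_cutoff = 0.5) {
  if (abs(det(W)) < 1e-15) stop("singular 'W'", call. = FALSE)
  if (is.null(track$delta1)) track <- unbias(track)
  disp <- W %*% rbind(track$delta1, track$delta2)    # cm
  t_out <- seq(track$times[1], track$times[length(track$times)],
               by = 1 / rate_out)
  deriv2 <- function(v) {
    v <- stats::approx(track$times, v, xout = t_out, rule = 2)$y
    v <- lowpass(v, rate_out, deriv_cutoff)
    d1 <- detrend(central_diff(v, 1 / rate_out), detrend_cutoff,
                  rate = rate_out)
    detrend(central_diff(d1, 1 / rate_out), detrend_cutoff, rate = rate_out)
  }
  a_fx <- deriv2(disp[1, ])
  a_fy <- deriv2(disp[2, ])
  list(
    a_fx = sampled_trace(a_fx, rate_out, units = "cm/s^2", label = "a_fx",
                         t0 = t_out[1]),
    a_fy = sampled_trace(a_fy, rate_out, units = "cm/s^2", label = "a_fy",
                         t0 = t_out[1]),
    dx_hat = disp[1, ], dy_hat = disp[2, ]
  )
}
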
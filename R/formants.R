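#' Linear-prediction analysis of one frame
#'
#' Fits a K-th order all-pole model to a pre-emphasized, tapered window by
#' the autocorrelation method (Toeplitz normal equations). The resulting
#' inverse-filter polynomial `B(z) = 1 - sum(b_i z^-i)` has all roots
#' inside the unit circle for non-degenerate frames.
#'
#' @param window_samples Numeric vector (already pre-emphasized and
#'   tapered); length must be at least `2 * order_K`.
#' @param order_K Prediction order.
#' @return Numeric vector `b` of length `order_K`, or `NULL` for a
#'   degenerate (silent) frame.
#' @export
lpc_frame <- function(window_samples, order_K = 10) {
  n <- length(window_samples)
  if (n < 2 * order_K)
    stop("window length must be >= 2 * order_K", call. = FALSE)
  x <- window_samples
  r <- vapply(0:order_K, function(k) {
    sum(x[1:(n - k)] * x[(k + 1):n])
  }, numeric(1))
  if (r[1] <= 0 || !all(is.finite(r))) return(NULL)  # silent frame
  R <- stats::toeplitz(r[1:order_K])
  # small diagonal ridge guards against numerically singular frames
  diag(R) <- diag(R) * (1 + 1e-9)
  b <- tryCatch(solve(R, r[2:(order_K + 1)]),
                error = function(e) NULL)
  if (is.null(b) || !all(is.finite(b))) return(NULL)
  b
}

#' Formant candidates from prediction-polynomial roots
#'
#' Finds the complex zeros `z_i = r_i exp(j phi_i)` of the inverse filter
#' and converts each root in the upper half-plane (`phi_i > 0`) to a
#' frequency `F_i = phi_i / (2 pi tau)` with `tau = 1/rate`, and a
#' bandwidth `-(rate/pi) log(r_i)`. Real positive roots map to F = 0 and
#' are excluded from the candidate list.
#'
#' @param coeffs Prediction coefficients `b` from [lpc_frame()].
#' @param rate Sampling rate in Hz.
#' @return Data frame with columns `F` (Hz, ascending) and `bandwidth`
#'   (Hz).
#' @export
roots_to_formants <- function(coeffs, rate) {
  k <- length(coeffs)
  # B(z) = 1 - sum b_i z^-i  <=>  z^k - b_1 z^{k-1} - ... - b_k = 0
  z <- polyroot(c(-rev(coeffs), 1))
  phi <- Arg(z)
  keep <- phi > 1e-9
  z <- z[keep]; phi <- phi[keep]
  f <- phi * rate / (2 * pi)
  bw <- -(rate / pi) * log(Mod(z))
  ord <- order(f)
  data.frame(F = f[ord], bandwidth = bw[ord])
}

#' Track the first two formants of 8 kHz speech
#'
#' Framewise LPC inverse filtering: 64 ms windows (512 samples at 8 kHz)
#' advanced every 2 ms (97% overlap), pre-emphasis 0.97, Hann taper.
#' Per frame, the two lowest-frequency root candidates with `F` in
#' \[150, 3500\] Hz and bandwidth below `bw_max` (default 400 Hz) are taken as (F1, F2).
#' Frames failing the candidate selection or an energy gate (frame RMS
#' below 5% of the utterance median RMS) are marked unvoiced; unvoiced
#' gaps no longer than `gap_ms` are linearly interpolated.
#'
#' @param speech_8k A [sampled_trace] at 8000 Hz.
#' @param win_ms Analysis window length, ms.
#' @param step_ms Frame advance, ms.
#' @param order_K LPC order (default 10 at 8 kHz).
#' @param f_range Admissible formant range, Hz.
#' @param bw_max Bandwidth ceiling for candidate selection, Hz.
#' @param gap_ms Longest unvoiced gap bridged by interpolation, ms.
#' @param energy_gate Voicing gate as a fraction of the median frame RMS.
#' @return Object of class `formant_track`: `times` (s, frame centers),
#'   `F1`, `F2` (Hz, `NA` on unbridged unvoiced frames), `voiced`
#'   (logical), `rate` (frame rate, Hz), `step` (s).
#' @export
track_formants <- function(speech_8k, win_ms = 64, step_ms = 2,
                           order_K = 10, f_range = c(150, 3500),
                           bw_max = 400, gap_ms = 20, energy_gate = 0.05) {
  stopifnot(is_trace(speech_8k))
  assert_rate(speech_8k, 8000, "speech")
  fs <- speech_8k$rate
  win <- round(win_ms / 1000 * fs)
  step <- round(step_ms / 1000 * fs)
  x <- speech_8k$samples
  n <- length(x)
  if (n < win) stop("recording shorter than one analysis window",
                    call. = FALSE)
  n_frames <- floor((n - win) / step) + 1L
  starts <- (seq_len(n_frames) - 1L) * step + 1L

  # pre-emphasis on the whole utterance, Hann taper per frame
  xe <- c(x[1], x[-1] - 0.97 * x[-n])
  taper <- 0.5 - 0.5 * cos(2 * pi * (seq_len(win) - 1) / (win - 1))

  rms <- vapply(starts, function(s0) {
    fr <- x[s0:(s0 + win - 1L)]
    sqrt(mean(fr^2))
  }, numeric(1))
  gate <- energy_gate * stats::median(rms)

  F1 <- rep(NA_real_, n_frames)
  F2 <- rep(NA_real_, n_frames)
  voiced <- logical(n_frames)
  for (i in seq_len(n_frames)) {
    if (rms[i] < gate) next
    fr <- xe[starts[i]:(starts[i] + win - 1L)] * taper
    b <- lpc_frame(fr, order_K)
    if (is.null(b)) next
    cand <- roots_to_formants(b, fs)
    cand <- cand[cand$F >= f_range[1] & cand$F <= f_range[2] &
                   cand$bandwidth < bw_max, , drop = FALSE]
    if (nrow(cand) < 2L) next
    F1[i] <- cand$F[1L]
    F2[i] <- cand$F[2L]
    voiced[i] <- TRUE
  }
  if (!any(voiced))
    stop("entirely unvoiced recording: no formant track", call. = FALSE)

  max_gap <- floor(gap_ms / step_ms)
  F1 <- bridge_gaps(F1, max_gap)
  F2 <- bridge_gaps(F2, max_gap)
  # 5-frame running median knocks out isolated mis-picked candidates
  F1 <- median_prefilter(F1)
  F2 <- median_prefilter(F2)

  times <- speech_8k$t0 + (starts - 1L + win / 2) / fs
  structure(
    list(times = times, F1 = F1, F2 = F2, voiced = voiced,
         rate = 1000 / step_ms, step = step_ms / 1000),
    class = "formant_track"
  )
}

# linear interpolation across interior NA runs of length <= max_gap
bridge_gaps <- function(v, max_gap) {
  isna <- is.na(v)
  if (!any(isna) || all(isna)) return(v)
  r <- rle(isna)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  filled <- stats::approx(which(!isna), v[!isna], xout = seq_along(v),
                          rule = 1)$y
  for (j in seq_along(r$lengths)) {
    if (r$values[j] && r$lengths[j] <= max_gap)
      v[starts[j]:ends[j]] <- filled[starts[j]:ends[j]]
  }
  v
}

median_prefilter <- function(v, k = 5L) {
  ok <- !is.na(v)
  if (sum(ok) > k) v[ok] <- stats::runmed(v[ok], k)
  v
}

#' @export
print.formant_track <- function(x, ...) {
  cat(sprintf("<formant_track> %d frames @ %g ms step, %.1f%% voiced\n",
              length(x$times), 1000 * x$step, 100 * mean(x$voiced)))
  if (any(x$voiced))
    cat(sprintf("  median F1 = %.0f Hz, F2 = %.0f Hz\n",
                stats::median(x$F1[x$voiced]),
                stats::median(x$F2[x$voiced])))
  invisible(x)
}

#' Unbiased formant oscillations and derivatives
#'
#' Subtracts the voiced-frame mean from each formant track to obtain the
#' unbiased oscillations `delta1 = F1 - mean(F1)`, `delta2 = F2 -
#' mean(F2)`, detrends them, band-limits them below `deriv_cutoff` and
#' differentiates by central differences on the frame grid, giving `dF1`,
#' `dF2` in Hz/s.
#'
#' The pre-differentiation low-pass matters: framewise LPC estimates carry
#' sample-to-sample jitter which differentiation on a 2 ms grid would
#' amplify by a factor of order the frame rate.
#'
#' @param track A `formant_track` with voiced coverage of at least 50%.
#' @param detrend_cutoff High-pass cutoff (Hz) removing slow drift.
#' @param deriv_cutoff Low-pass cutoff (Hz) applied before
#'   differentiation; the default 15 Hz keeps the first six harmonics of
#'   the fastest normokinetic syllable rate while rejecting frame-level
#'   estimation jitter.
#' @return The track with added fields `delta1`, `delta2` (Hz), `dF1`,
#'   `dF2` (Hz/s).
#' @export
unbias <- function(track, detrend_cutoff = 0.5, deriv_cutoff = 15) {
  stopifnot(inherits(track, "formant_track"))
  if (mean(track$voiced) < 0.5)
    stop("voiced coverage below 50%", call. = FALSE)
  frame_rate <- track$rate
  fill <- function(v) {
    ok <- !is.na(v)
    stats::approx(which(ok), v[ok], xout = seq_along(v), rule = 2)$y
  }
  for (nm in c("F1", "F2")) {
    f <- fill(track[[nm]])
    delta <- f - mean(track[[nm]][track$voiced], na.rm = TRUE)
    sm <- lowpass(detrend(delta, detrend_cutoff, rate = frame_rate),
                  frame_rate, deriv_cutoff)
    d <- central_diff(sm, 1 / frame_rate)
    i <- if (nm == "F1") "1" else "2"
    track[[paste0("delta", i)]] <- delta
    track[[paste0("dF", i)]] <- d
  }
  track
}

central_diff <- function(x, dt) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- d[2]; d[n] <- d[n - 1]
  d
}
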
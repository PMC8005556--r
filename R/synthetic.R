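#' Define a synthetic diadochokinetic articulation scenario
#'
#' A scenario fixes every parameter of one synthetic participant performing
#' the repeated \[aI\] exercise: the jaw-tongue reference point oscillation,
#' the linear articulatory-to-acoustic projection, the accelerometer
#' mounting angle, the glottal source, noise levels and the lag chain.
#'
#' The default projection gains follow the printed "x 10^3" convention of
#' articulatory gain tables, i.e. gains expressed in Hz per metre divided by
#' 1000: the vertical column defaults to `a21 = -55.5` (Hz/m x 10^3, jaw up
#' lowers F1) and `a22 = 110` (jaw up raises F2). Internally gains are kept
#' in Hz/cm (`-555` and `1100`). The horizontal column is a synthetic
#' convention set to 20% of the magnitude of the vertical gains with
#' positive sign. A 2 mm peak-to-peak vertical oscillation under the default
#' gains produces a ~111 Hz peak-to-peak swing in F1 and ~220 Hz in F2.
#'
#' The `hypokinesia` factor in (0, 1] scales both the oscillation
#' amplitudes and the syllable rate; 1 is normokinetic, smaller values
#' emulate the reduced articulatory range and rate of hypokinetic
#' dysarthria.
#'
#' @param duration Recording length in seconds.
#' @param syllable_rate \[aI\] repetitions per second, in \[1, 5\].
#' @param amp_y Vertical half-amplitude of the jaw-tongue reference point,
#'   cm (default 0.1 cm = 2 mm peak-to-peak).
#' @param amp_x Horizontal half-amplitude, cm.
#' @param hypokinesia Scalar in (0, 1]; scales amplitude and syllable rate.
#' @param theta Accelerometer mounting angle in rad, in (-pi/2, pi/2).
#' @param A_true 2x2 projection matrix in Hz/cm mapping `(dx, dy)` (cm) to
#'   `(dF1, dF2)` (Hz); column 1 is the horizontal gains, column 2 the
#'   vertical. Must be invertible with `sign(A[1,2]) = -1`,
#'   `sign(A[2,2]) = +1`.
#' @param F_base Resting (F1, F2) in Hz, `0 < F1 < F2`.
#' @param f0 Mean glottal pitch in Hz (default 110, an aged male-typical
#'   value whose harmonics sample the F1 region densely; see the
#'   vignette).
#' @param noise_accel Accelerometer white-noise RMS, cm/s^2.
#' @param noise_semg Relative sEMG measurement-noise RMS (fraction of the
#'   tonic envelope level).
#' @param lag_ms Neuromotor-to-acoustic lag: the formant tracks are delayed
#'   by this much relative to the displacement (default 16 ms).
#' @param shape `"raised_cosine"` (asymmetric open/close syllable cycles,
#'   the default) or `"sine"` (pure sinusoid, for closed-form checks).
#' @param duty Fraction of the cycle spent in the opening phase for the
#'   raised-cosine shape.
#' @param seed Integer seed; `make_recording()` is deterministic given it.
#' @return An object of class `articulation_scenario` (a validated list).
#' @export
articulation_scenario <- function(duration = 6, syllable_rate = 2.5,
                                  amp_y = 0.1, amp_x = 0.05,
                                  hypokinesia = 1, theta = 0.15,
                                  A_true = NULL,
                                  F_base = c(600, 1400), f0 = 110,
                                  noise_accel = 2, noise_semg = 0.1,
                                  lag_ms = 16, shape = "raised_cosine",
                                  duty = 0.6, seed = 1) {
  if (is.null(A_true))
    A_true <- matrix(c(111, 220, -555, 1100), 2, 2)
  stopifnot(duration > 0,
            syllable_rate >= 1, syllable_rate <= 5,
            hypokinesia > 0, hypokinesia <= 1,
            abs(theta) < pi / 2,
            length(F_base) == 2, F_base[1] > 0, F_base[1] < F_base[2],
            f0 > 0, duty > 0, duty < 1)
  shape <- match.arg(shape, c("raised_cosine", "sine"))
  if (!is.matrix(A_true) || any(dim(A_true) != 2) ||
      abs(det(A_true)) < 1e-12)
    stop("'A_true' must be an invertible 2x2 matrix", call. = FALSE)
  if (sign(A_true[1, 2]) != -1 || sign(A_true[2, 2]) != 1)
    stop("vertical gains must satisfy sign(a21) = -1, sign(a22) = +1",
         call. = FALSE)
  structure(
    list(duration = duration, syllable_rate = syllable_rate,
         amp_y = amp_y, amp_x = amp_x, hypokinesia = hypokinesia,
         theta = theta, A_true = A_true, F_base = F_base, f0 = f0,
         noise_accel = noise_accel, noise_semg = noise_semg,
         lag_ms = lag_ms, shape = shape, duty = duty,
         seed = as.integer(seed)),
    class = "articulation_scenario"
  )
}

#' @export
print.articulation_scenario <- function(x, ...) {
  cat(sprintf(
    "<articulation_scenario> %.3g s, %.3g syll/s, amp (x,y) = (%.3g, %.3g) cm\n",
    x$duration, x$syllable_rate, x$amp_x, x$amp_y))
  cat(sprintf("  hypokinesia %.3g, theta %.3g rad, f0 %.3g Hz, shape %s, seed %d\n",
              x$hypokinesia, x$theta, x$f0, x$shape, x$seed))
  cat(sprintf("  gains (x10^3 Hz/m): a21 = %.4g, a22 = %.4g; lag %.3g ms\n",
              x$A_true[1, 2] / 10, x$A_true[2, 2] / 10, x$lag_ms))
  invisible(x)
}

# Periodic zero-mean syllable waveform evaluated at cycle phase u in [0, 1).
# Opening phase (jaw drops, +amp -> -amp) occupies `duty` of the cycle,
# closing (masseter pull-up) the remainder, both as half raised cosines;
# each half-cosine has exactly zero mean so the trajectory is unbiased.
syllable_shape <- function(u, duty) {
  u <- u %% 1
  y <- numeric(length(u))
  open <- u < duty
  y[open] <- cos(pi * u[open] / duty)
  y[!open] <- -cos(pi * (u[!open] - duty) / (1 - duty))
  y
}

#' Generate the jaw-tongue reference-point trajectory
#'
#' Produces the sagittal displacement pair `(dx, dy)` in cm of the
#' jaw-tongue reference point for a scenario. The vertical component is a
#' zero-mean shaped oscillation at the hypokinesia-scaled syllable rate with
#' hypokinesia-scaled half-amplitude; the horizontal component uses `amp_x`
#' and a fixed quarter-cycle phase lead.
#'
#' @param scenario An [articulation_scenario].
#' @param rate Sampling rate of the returned trajectory, Hz.
#' @return List with `t` (s), `dx`, `dy` (cm), `rate`, and the effective
#'   amplitude/rate after hypokinesia scaling.
#' @export
make_trajectory <- function(scenario, rate = 2500) {
  stopifnot(inherits(scenario, "articulation_scenario"))
  f_eff <- scenario$syllable_rate * scenario$hypokinesia
  ay <- scenario$amp_y * scenario$hypokinesia
  ax <- scenario$amp_x * scenario$hypokinesia
  t <- seq(0, scenario$duration, by = 1 / rate)
  if (scenario$shape == "sine") {
    dy <- ay * sin(2 * pi * f_eff * t)
    dx <- ax * sin(2 * pi * f_eff * t + pi / 2)
  } else {
    u <- f_eff * t
    dy <- ay * syllable_shape(u, scenario$duty)
    dx <- ax * syllable_shape(u + 0.25, scenario$duty)
  }
  list(t = t, dx = dx, dy = dy, rate = rate, amp_y_eff = ay,
       amp_x_eff = ax, rate_eff = f_eff)
}

#' Project a trajectory onto formant tracks
#'
#' Applies the linear articulatory-to-acoustic map: `F_i(t) = F_base_i +
#' (A %*% c(dx, dy))(t - lag)`. With the default sign structure an upward
#' vertical displacement lowers F1 and raises F2. Outputs are clipped to
#' \[150, 3500\] Hz; a warning is raised if clipping engages on more than 1%
#' of samples (oscillation amplitudes too large for the linear regime).
#'
#' @param traj Trajectory from [make_trajectory()].
#' @param A_true 2x2 projection matrix, Hz/cm.
#' @param F_base Resting (F1, F2), Hz.
#' @param lag_ms Delay of the formant response relative to the
#'   displacement, ms.
#' @return List of class `formant_truth`: `t`, `F1`, `F2` (Hz) on the
#'   trajectory grid, plus `rate`.
#' @export
trajectory_to_formants <- function(traj, A_true, F_base, lag_ms = 0) {
  if (abs(det(A_true)) < 1e-12)
    stop("'A_true' must be invertible", call. = FALSE)
  lag_s <- lag_ms / 1000
  # displacement evaluated at t - lag (constant-extended at the left edge)
  dxl <- stats::approx(traj$t, traj$dx, xout = traj$t - lag_s, rule = 2)$y
  dyl <- stats::approx(traj$t, traj$dy, xout = traj$t - lag_s, rule = 2)$y
  dF <- A_true %*% rbind(dxl, dyl)
  F1 <- F_base[1] + dF[1, ]
  F2 <- F_base[2] + dF[2, ]
  clipped <- mean(F1 < 150 | F1 > 3500 | F2 < 150 | F2 > 3500)
  if (clipped > 0.01)
    warning(sprintf("formant clipping on %.1f%% of samples; amplitudes too large",
                    100 * clipped))
  F1 <- pmin(pmax(F1, 150), 3500)
  F2 <- pmin(pmax(F2, 150), 3500)
  structure(list(t = traj$t, F1 = F1, F2 = F2, rate = traj$rate),
            class = "formant_truth")
}

#' Synthesize source-filter speech from formant tracks
#'
#' Runs a glottal pulse train at `f0` through a time-varying all-pole
#' filter with two resonances at (F1(t), F2(t)) and fixed bandwidths.
#' Coefficients are updated every 2 ms (piecewise-constant blocks); the
#' output is peak-normalized to 0.9.
#'
#' The source models three traits of natural (and especially aged)
#' phonation that matter for downstream spectral-envelope estimation:
#' cycle-to-cycle period jitter, slow multiplicative f0 drift, and an
#' aspiration-noise floor. A perfectly periodic impulse train would
#' produce a line spectrum with no inter-harmonic energy — the worst case
#' for linear-prediction formant estimation whenever formant excursions
#' are smaller than the harmonic spacing.
#'
#' @param track A `formant_truth` (or any list with `t`, `F1`, `F2`).
#' @param f0 Mean pitch in Hz; an amplitude of 0 yields silence.
#' @param fs Output sampling rate, Hz; must be at least `2 * max(F2)`.
#' @param bandwidths Resonance bandwidths (B1, B2) in Hz, both > 0.
#' @param amplitude Excitation amplitude (0 disables the source).
#' @param jitter Relative SD of cycle-to-cycle period perturbation.
#' @param f0_drift Relative amplitude of slow (~0.1-0.3 Hz) pitch wander.
#' @param aspiration Aspiration-noise level relative to the pulse train.
#' @return A [sampled_trace] at `fs`.
#' @export
synthesize_speech <- function(track, f0, fs = 50000,
                              bandwidths = c(80, 120), amplitude = 1,
                              jitter = 0.02, f0_drift = 0.04,
                              aspiration = 0.05) {
  if (any(bandwidths <= 0))
    stop("resonance bandwidths must be > 0 (unstable filter pole)",
         call. = FALSE)
  if (fs < 2 * max(track$F2))
    stop("'fs' must be at least twice max(F2)", call. = FALSE)
  # the resonator cascade runs at a speech-typical rate: at very high
  # sampling rates all formant poles crowd near z = 1 and their skirts
  # visibly shift each other's spectral peaks
  fs_syn <- min(fs, 10000)
  dur <- max(track$t) - min(track$t)
  n <- floor(dur * fs_syn) + 1L
  t <- min(track$t) + (seq_len(n) - 1L) / fs_syn

  # glottal source: phase-accumulated pitch pulses with jitter and drift,
  # plus an aspiration-noise floor (scaled so pulse and noise power keep a
  # fixed ratio across f0)
  x <- numeric(n)
  if (amplitude != 0) {
    ph <- stats::runif(2, 0, 2 * pi)
    rel_t <- t - t[1]
    drift_of <- function(tt) {
      1 + f0_drift * (0.6 * sin(2 * pi * 0.25 * tt + ph[1]) +
                        0.4 * sin(2 * pi * 0.11 * tt + ph[2]))
    }
    pos <- 1
    while (pos <= n) {
      x[round(pos)] <- amplitude
      f_now <- f0 * drift_of(rel_t[min(n, round(pos))])
      pos <- pos + fs_syn / f_now * (1 + jitter * stats::rnorm(1))
    }
    if (aspiration > 0)
      x <- x + amplitude * aspiration * sqrt(f0 / fs_syn) * stats::rnorm(n)
  }

  block <- max(1L, round(0.002 * fs_syn))
  starts <- seq(1L, n, by = block)
  F1b <- stats::approx(track$t, track$F1, xout = t[pmin(starts + block %/% 2, n)],
                       rule = 2)$y
  F2b <- stats::approx(track$t, track$F2, xout = t[pmin(starts + block %/% 2, n)],
                       rule = 2)$y
  r1 <- exp(-pi * bandwidths[1] / fs_syn)
  r2 <- exp(-pi * bandwidths[2] / fs_syn)

  y <- numeric(n)
  state <- numeric(4)  # most recent output first
  for (i in seq_along(starts)) {
    idx <- starts[i]:min(starts[i] + block - 1L, n)
    q1 <- c(2 * r1 * cos(2 * pi * F1b[i] / fs_syn), -r1^2)
    q2 <- c(2 * r2 * cos(2 * pi * F2b[i] / fs_syn), -r2^2)
    # cascade of the two resonators: AR(4) coefficients from the product
    # (1 - q11 z - q12 z^2)(1 - q21 z - q22 z^2)
    a <- c(q1[1] + q2[1],
           q1[2] + q2[2] - q1[1] * q2[1],
           -(q1[1] * q2[2] + q1[2] * q2[1]),
           -q1[2] * q2[2])
    yb <- stats::filter(x[idx], a, method = "recursive", init = state)
    y[idx] <- yb
    state <- rev(y[max(1L, idx[length(idx)] - 3L):idx[length(idx)]])
  }
  if (fs > fs_syn) {
    n_out <- floor(dur * fs) + 1L
    t_out <- min(track$t) + (seq_len(n_out) - 1L) / fs
    y <- stats::spline(t, y, xout = t_out)$y
  }
  peak <- max(abs(y))
  if (peak > 0) y <- 0.9 * y / peak
  sampled_trace(y, fs, units = "dimensionless", label = "speech",
                t0 = min(track$t))
}

#' Device-frame accelerations from a trajectory
#'
#' Differentiates the sagittal trajectory twice, rotates the acceleration
#' into the accelerometer device frame (mounting angle `theta`), adds the
#' gravity projection as a DC component, and white measurement noise.
#'
#' The device frame relates to the sagittal reference frame by
#' `a_device = R(theta) %*% a_ref` with
#' `R(theta) = rbind(c(cos, sin), c(-sin, cos))`, so a static sensor reads
#' `(g sin(theta), g cos(theta))`.
#'
#' @param traj Trajectory from [make_trajectory()].
#' @param theta Mounting angle, rad, in (-pi/2, pi/2).
#' @param g Gravity in cm/s^2 (981 keeps all kinematics in cm units).
#' @param noise_rms White-noise RMS added per axis, cm/s^2.
#' @param seed Optional seed for the noise draw.
#' @return List with [sampled_trace] elements `accel_x`, `accel_y`
#'   (device frame, cm/s^2) and the noiseless sagittal accelerations
#'   `ax_ref`, `ay_ref`.
#' @export
trajectory_to_accel <- function(traj, theta, g = 981, noise_rms = 0,
                                seed = NULL) {
  stopifnot(abs(theta) < pi / 2)
  if (!is.null(seed)) set.seed(seed)
  dt <- 1 / traj$rate
  ax <- second_diff(traj$dx, dt)
  ay <- second_diff(traj$dy, dt)
  ct <- cos(theta); st <- sin(theta)
  dev_x <- ct * ax + st * (ay + g)
  dev_y <- -st * ax + ct * (ay + g)
  n <- length(ax)
  if (noise_rms > 0) {
    dev_x <- dev_x + stats::rnorm(n, 0, noise_rms)
    dev_y <- dev_y + stats::rnorm(n, 0, noise_rms)
  }
  list(
    accel_x = sampled_trace(dev_x, traj$rate, units = "cm/s^2",
                            label = "a_x"),
    accel_y = sampled_trace(dev_y, traj$rate, units = "cm/s^2",
                            label = "a_y"),
    ax_ref = ax, ay_ref = ay
  )
}

second_diff <- function(x, dt) {
  n <- length(x)
  d2 <- numeric(n)
  d2[2:(n - 1)] <- (x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]) / dt^2
  d2[1] <- d2[2]; d2[n] <- d2[n - 1]
  d2
}

#' Synthesize surface EMG from an activation envelope
#'
#' Generates an sEMG trace as a zero-mean noise carrier band-passed to
#' 20-250 Hz, amplitude-modulated by a nonnegative activation envelope,
#' plus white measurement noise. The expected rectified amplitude is
#' proportional to the activation.
#'
#' @param activation Nonnegative numeric vector (band-limited below 25 Hz).
#' @param fs Sampling rate, Hz.
#' @param noise_rms Measurement-noise RMS (same units as the output).
#' @param seed Optional seed.
#' @param band Carrier passband in Hz.
#' @return A [sampled_trace] (units mV).
#' @export
activation_to_semg <- function(activation, fs = 2500, noise_rms = 0,
                               seed = NULL, band = c(20, 250)) {
  if (any(activation < 0)) stop("'activation' must be nonnegative",
                                call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- length(activation)
  carrier <- stats::rnorm(n)
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  carrier <- zero_phase(carrier, bf, ceiling(4 * fs / band[1]))
  carrier <- carrier / stats::sd(carrier)
  s <- activation * carrier
  if (noise_rms > 0) s <- s + stats::rnorm(n, 0, noise_rms)
  sampled_trace(s, fs, units = "mV", label = "semg")
}

#' Generate one synchronized multimodal recording
#'
#' Composes the full synthetic participant: speech at 50 kHz, device-frame
#' accelerations and sEMG at 2.5 kHz, and a ground-truth block. The lag
#' chain is injected as: the masseter drive (and hence the ECMF) leads the
#' jaw acceleration by 2 ms, and the formant tracks lag the displacement by
#' `scenario$lag_ms` (default 16 ms).
#'
#' The sEMG amplitude envelope carries the time-derivative of the net
#' vertical force correlate on a tonic pedestal, so that the analysis-side
#' ECMF (detrended integral of the rectified sEMG) reconstructs the force
#' correlate itself; see the package vignette for the rationale.
#'
#' @param scenario An [articulation_scenario].
#' @return Object of class `multimodal_recording`: traces `speech`
#'   (50 kHz), `accel_x`, `accel_y`, `semg` (2.5 kHz) and a `truth` list
#'   (trajectory, formant tracks, force correlate, sEMG envelope, theta,
#'   A_true, injected lags). Deterministic for a fixed scenario seed.
#' @export
make_recording <- function(scenario) {
  stopifnot(inherits(scenario, "articulation_scenario"))
  set.seed(scenario$seed)
  fs_acc <- 2500
  traj <- make_trajectory(scenario, rate = fs_acc)

  truth_track <- trajectory_to_formants(traj, scenario$A_true,
                                        scenario$F_base, scenario$lag_ms)
  speech <- synthesize_speech(truth_track, scenario$f0, fs = 50000)

  acc <- trajectory_to_accel(traj, scenario$theta, g = 981,
                             noise_rms = scenario$noise_accel)

  # net vertical force correlate (unit effective mass), band-limited < 25 Hz
  force <- lowpass(acc$ay_ref, fs_acc, 25)
  lead <- round(0.002 * fs_acc)  # 2 ms masseter-drive lead
  force_adv <- c(force[(lead + 1):length(force)],
                 rep(force[length(force)], lead))
  dforce <- central_diff(force_adv, 1 / fs_acc)
  env0 <- 0.5
  denom <- max(abs(dforce))
  env <- if (denom > 0) env0 * (1 + 0.9 * dforce / denom) else
    rep(env0, length(dforce))
  semg <- activation_to_semg(env, fs = fs_acc,
                             noise_rms = scenario$noise_semg * env0)

  truth <- list(
    t = traj$t, dx = traj$dx, dy = traj$dy,
    formants = truth_track,
    force = force_adv,       # ECMF ground truth (leads acceleration by 2 ms)
    activation = env,        # sEMG amplitude envelope
    theta = scenario$theta, A_true = scenario$A_true,
    lag_formant_ms = scenario$lag_ms, lag_emg_ms = 2
  )
  structure(
    list(speech = speech, accel_x = acc$accel_x, accel_y = acc$accel_y,
         semg = semg, truth = truth, scenario = scenario),
    class = "multimodal_recording"
  )
}

#' @export
print.multimodal_recording <- function(x, ...) {
  cat(sprintf("<multimodal_recording> %.3g s: speech @ %g Hz; a_x, a_y, semg @ %g Hz\n",
              x$scenario$duration, x$speech$rate, x$accel_x$rate))
  cat(sprintf("  hypokinesia %.3g, lags: drive->accel 2 ms, accel->formants %g ms\n",
              x$scenario$hypokinesia, x$scenario$lag_ms))
  invisible(x)
}

#' Write a recording to a participant directory
#'
#' Writes `speech.wav` (16-bit PCM), `channels.csv` (t, a_x, a_y, semg),
#' `truth.csv` (500 Hz ground truth) and `scenario.yaml`.
#'
#' @param rec A `multimodal_recording`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "multimodal_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_wav(rec$speech, file.path(dir, "speech.wav"))
  write_channels(list(a_x = rec$accel_x, a_y = rec$accel_y, semg = rec$semg),
                 file.path(dir, "channels.csv"))
  keep <- seq(1L, length(rec$truth$t), by = 5L)  # 2500 -> 500 Hz
  truth_df <- data.frame(
    t = rec$truth$t[keep], dx = rec$truth$dx[keep], dy = rec$truth$dy[keep],
    F1 = rec$truth$formants$F1[keep], F2 = rec$truth$formants$F2[keep],
    force = rec$truth$force[keep], activation = rec$truth$activation[keep]
  )
  utils::write.csv(signif(truth_df, 7), file.path(dir, "truth.csv"),
                   row.names = FALSE)
  sc <- rec$scenario
  sc$A_true <- as.numeric(sc$A_true)
  yaml::write_yaml(unclass(sc), file.path(dir, "scenario.yaml"))
  invisible(dir)
}

#' Read a recording back from a participant directory
#'
#' @param dir Directory written by [write_recording()].
#' @return A `multimodal_recording` (the truth block at 500 Hz).
#' @export
read_recording <- function(dir) {
  sc <- yaml::read_yaml(file.path(dir, "scenario.yaml"))
  sc$A_true <- matrix(sc$A_true, 2, 2)
  scenario <- do.call(articulation_scenario,
                      sc[names(sc) %in% names(formals(articulation_scenario))])
  speech <- read_wav(file.path(dir, "speech.wav"))
  ch <- read_channels(file.path(dir, "channels.csv"),
                      units = c(a_x = "cm/s^2", a_y = "cm/s^2", semg = "mV"),
                      required = c("a_x", "a_y", "semg"))
  truth_df <- utils::read.csv(file.path(dir, "truth.csv"))
  truth <- list(
    t = truth_df$t, dx = truth_df$dx, dy = truth_df$dy,
    formants = structure(list(t = truth_df$t, F1 = truth_df$F1,
                              F2 = truth_df$F2, rate = 500),
                         class = "formant_truth"),
    force = truth_df$force, activation = truth_df$activation,
    theta = scenario$theta, A_true = scenario$A_true,
    lag_formant_ms = scenario$lag_ms, lag_emg_ms = 2
  )
  structure(
    list(speech = speech, accel_x = ch$a_x, accel_y = ch$a_y,
         semg = ch$semg, truth = truth, scenario = scenario),
    class = "multimodal_recording"
  )
}

#' Generate a synthetic study cohort
#'
#' Builds scenarios for `n_controls` normokinetic and `n_pd` hypokinetic
#' participants with seeded inter-participant variability in amplitude,
#' syllable rate, pitch, mounting angle, resting formants and projection
#' gains. Patients share the same variability model plus the `hypokinesia`
#' factor.
#'
#' @param n_controls,n_pd Cohort sizes.
#' @param hypokinesia Hypokinesia factor applied to the patient cohort.
#' @param seed Master seed; per-participant seeds are derived from it.
#' @param duration Recording length per participant, seconds.
#' @return Data-frame-like list of class `study_cohort`: `id`, `cohort`
#'   (`"control"` / `"pd"`), and a `scenarios` list.
#' @export
make_cohort <- function(n_controls = 8, n_pd = 8, hypokinesia = 0.4,
                        seed = 7, duration = 6) {
  set.seed(seed)
  n <- n_controls + n_pd
  ids <- c(sprintf("C%02d", seq_len(n_controls)),
           sprintf("P%02d", seq_len(n_pd)))
  cohort <- rep(c("control", "pd"), c(n_controls, n_pd))
  sub_seeds <- sample.int(2^31 - 2, n)
  scenarios <- vector("list", n)
  for (i in seq_len(n)) {
    gy1 <- -555 * stats::runif(1, 0.8, 1.2)
    gy2 <- 1100 * stats::runif(1, 0.8, 1.2)
    A <- matrix(c(0.2 * abs(gy1), 0.2 * abs(gy2), gy1, gy2), 2, 2)
    scenarios[[i]] <- articulation_scenario(
      duration = duration,
      syllable_rate = 2.5 * stats::runif(1, 0.9, 1.1),
      amp_y = 0.1 * stats::runif(1, 0.85, 1.15),
      amp_x = 0.05 * stats::runif(1, 0.85, 1.15),
      hypokinesia = if (cohort[i] == "pd") hypokinesia else 1,
      theta = stats::rnorm(1, 0.15, 0.05),
      A_true = A,
      F_base = c(600 * stats::runif(1, 0.95, 1.05),
                 1400 * stats::runif(1, 0.95, 1.05)),
      f0 = stats::runif(1, 100, 160),
      seed = sub_seeds[i]
    )
  }
  structure(list(id = ids, cohort = cohort, scenarios = scenarios),
            class = "study_cohort")
}

#' @export
print.study_cohort <- function(x, ...) {
  cat(sprintf("<study_cohort> %d participants (%d control, %d pd)\n",
              length(x$id), sum(x$cohort == "control"),
              sum(x$cohort == "pd")))
  invisible(x)
}
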
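test_that("trajectory amplitude follows the scenario and the hypokinesia scaling", {
  sc1 <- articulation_scenario(amp_y = 0.2, hypokinesia = 1, seed = 1)
  expect_equal(max(abs(make_trajectory(sc1)$dy)), 0.2, tolerance = 1e-6)
  sc2 <- articulation_scenario(amp_y = 0.2, hypokinesia = 0.4, seed = 1)
  tr2 <- make_trajectory(sc2)
  expect_equal(max(abs(tr2$dy)), 0.08, tolerance = 1e-6)
  expect_equal(tr2$rate_eff, 0.4 * sc2$syllable_rate)
  # zero mean by construction
  expect_lt(abs(mean(make_trajectory(sc1)$dy)), 1e-3)
})

test_that("pure-sine trajectory has the closed-form peak vertical speed", {
  sc <- articulation_scenario(amp_y = 0.2, amp_x = 0, syllable_rate = 2.5,
                              shape = "sine", duration = 4, seed = 1)
  traj <- make_trajectory(sc)
  v <- diff(traj$dy) * traj$rate
  expect_equal(max(abs(v)), 2 * pi * 2.5 * 0.2, tolerance = 0.001)
})

test_that("trajectory_to_formants applies the linear map with the table signs", {
  sc <- articulation_scenario(seed = 1)
  traj <- make_trajectory(sc)
  # zero displacement -> resting formants everywhere
  traj0 <- traj; traj0$dx <- traj0$dx * 0; traj0$dy <- traj0$dy * 0
  ft0 <- trajectory_to_formants(traj0, sc$A_true, c(600, 1400))
  expect_true(all(ft0$F1 == 600) && all(ft0$F2 == 1400))
  # a +0.001 cm upward step through the vertical column: dF1 = a21/1000 per cm
  traj1 <- traj0; traj1$dy <- rep(0.001, length(traj0$dy))
  ft1 <- trajectory_to_formants(traj1, sc$A_true, c(600, 1400))
  expect_equal(ft1$F1[100], 600 - 0.555, tolerance = 1e-9)
  expect_equal(ft1$F2[100], 1400 + 1.1, tolerance = 1e-9)
  # upward motion lowers F1 and raises F2 under the default matrix
  ft <- trajectory_to_formants(traj, sc$A_true, c(600, 1400))
  up <- traj$dy > 0.05
  expect_lt(mean(ft$F1[up]), 600)
  expect_gt(mean(ft$F2[up]), 1400)
})

test_that("the inverse projection recovers the trajectory exactly without lag", {
  sc <- articulation_scenario(seed = 2)
  traj <- make_trajectory(sc)
  ft <- trajectory_to_formants(traj, sc$A_true, sc$F_base, lag_ms = 0)
  W <- solve(sc$A_true)
  rec <- W %*% rbind(ft$F1 - sc$F_base[1], ft$F2 - sc$F_base[2])
  expect_equal(rec[1, ], traj$dx, tolerance = 1e-9)
  expect_equal(rec[2, ], traj$dy, tolerance = 1e-9)
})

test_that("formant clipping warns when amplitudes leave the linear regime", {
  sc <- articulation_scenario(seed = 1, amp_y = 0.1)
  traj <- make_trajectory(sc)
  huge <- matrix(c(111, 220, -55500, 110000), 2, 2)
  expect_warning(trajectory_to_formants(traj, huge, c(600, 1400)),
                 "clipping")
})

test_that("synthesized speech carries the commanded resonances", {
  set.seed(5)
  cf <- structure(list(t = seq(0, 1, by = 1 / 500),
                       F1 = rep(700, 501), F2 = rep(1200, 501), rate = 500),
                  class = "formant_truth")
  sp <- synthesize_speech(cf, f0 = 110, fs = 50000)
  expect_equal(sp$rate, 50000)
  expect_equal(max(abs(sp$samples)), 0.9, tolerance = 1e-9)
  tr <- track_formants(resample_antialias(sp, 8000, 4000))
  expect_equal(median(tr$F1, na.rm = TRUE), 700, tolerance = 30 / 700)
  expect_equal(median(tr$F2, na.rm = TRUE), 1200, tolerance = 30 / 1200)
})

test_that("zero source amplitude yields silence and bad bandwidths error", {
  cf <- structure(list(t = seq(0, 0.5, by = 1 / 500),
                       F1 = rep(700, 251), F2 = rep(1200, 251), rate = 500),
                  class = "formant_truth")
  sp <- synthesize_speech(cf, f0 = 110, amplitude = 0)
  expect_true(all(sp$samples == 0))
  expect_error(synthesize_speech(cf, 110, bandwidths = c(-1, 120)),
               "unstable|bandwidth")
})

test_that("a chirped F1 is tracked monotonically", {
  set.seed(8)
  t <- seq(0, 2, by = 1 / 500)
  cf <- structure(list(t = t, F1 = seq(600, 900, length.out = length(t)),
                       F2 = rep(1800, length(t)), rate = 500),
                  class = "formant_truth")
  sp8 <- resample_antialias(synthesize_speech(cf, 110), 8000, 4000)
  tr <- track_formants(sp8)
  sm <- lowpass(tr$F1, 500, 2)
  i <- seq(200, length(sm) - 200, by = 100)
  expect_true(all(diff(sm[i]) > 0))
})

test_that("device-frame accelerations carry gravity, rotation and closed-form dynamics", {
  sc <- articulation_scenario(seed = 1, duration = 2)
  traj0 <- make_trajectory(sc)
  traj0$dx <- traj0$dx * 0; traj0$dy <- traj0$dy * 0
  # static, theta = 0: all gravity on y
  acc <- trajectory_to_accel(traj0, theta = 0, noise_rms = 0)
  expect_equal(acc$accel_y$samples, rep(981, length(traj0$t)))
  expect_equal(acc$accel_x$samples, rep(0, length(traj0$t)))
  # static, theta near pi/2: gravity swaps onto x
  acc2 <- trajectory_to_accel(traj0, theta = pi / 2 - 1e-9, noise_rms = 0)
  expect_equal(acc2$accel_x$samples[1], 981, tolerance = 1e-6)
  expect_equal(acc2$accel_y$samples[1], 0, tolerance = 1e-3)
  # sine dy: device-y dynamic amplitude = Y (2 pi f)^2 cos(theta)
  scs <- articulation_scenario(amp_y = 0.2, amp_x = 0, syllable_rate = 2.5,
                               shape = "sine", duration = 4, seed = 1)
  trajs <- make_trajectory(scs)
  acc3 <- trajectory_to_accel(trajs, theta = 0.3, noise_rms = 0)
  dyn <- acc3$accel_y$samples - mean(acc3$accel_y$samples)
  expect_equal(max(abs(dyn)), 0.2 * (2 * pi * 2.5)^2 * cos(0.3),
               tolerance = 0.01)
})

test_that("sEMG is an activation-modulated band-limited carrier", {
  fs <- 2500
  n <- 4 * fs
  # zero activation: output is pure measurement noise at the given RMS
  s0 <- activation_to_semg(rep(0, n), fs, noise_rms = 0.05, seed = 3)
  expect_equal(sqrt(mean(s0$samples^2)), 0.05, tolerance = 0.05)
  # constant activation: moving RMS flat within 10% (2 s segments)
  s1 <- activation_to_semg(rep(2, 8 * fs), fs, noise_rms = 0, seed = 3)
  seg <- split(s1$samples, rep(1:4, each = 2 * fs))
  rms <- vapply(seg, function(v) sqrt(mean(v^2)), numeric(1))
  expect_lt((max(rms) - min(rms)) / mean(rms), 0.1)
  # two equal bursts give equal rectified-integral increments within 10%
  act <- rep(0, n)
  act[fs:(2 * fs)] <- 1
  act[(3 * fs):(4 * fs - 1)] <- 1
  s2 <- activation_to_semg(act, fs, noise_rms = 0, seed = 4)
  inc1 <- sum(abs(s2$samples[fs:(2 * fs)])) / fs
  inc2 <- sum(abs(s2$samples[(3 * fs):(4 * fs - 1)])) / fs
  expect_equal(inc1, inc2, tolerance = 0.1)
  expect_error(activation_to_semg(c(-1, 1), fs), "nonnegative")
})

test_that("make_recording is seed-deterministic and conserves ground truth", {
  sc <- articulation_scenario(duration = 2, seed = 99)
  r1 <- make_recording(sc)
  r2 <- make_recording(sc)
  expect_identical(r1$speech$samples, r2$speech$samples)
  expect_identical(r1$semg$samples, r2$semg$samples)
  expect_identical(r1$truth$A_true, sc$A_true)
  expect_identical(r1$truth$theta, sc$theta)
  expect_identical(r1$truth$lag_formant_ms, sc$lag_ms)
  # channels cover the same span
  expect_equal(max(trace_time(r1$speech)), max(trace_time(r1$semg)),
               tolerance = 1 / 2500)
})

test_that("a recording survives the directory round trip", {
  dir <- withr::local_tempdir()
  sc <- articulation_scenario(duration = 2, seed = 5)
  rec <- make_recording(sc)
  write_recording(rec, dir)
  expect_setequal(list.files(dir), c("speech.wav", "channels.csv",
                                     "truth.csv", "scenario.yaml"))
  back <- read_recording(dir)
  expect_equal(back$scenario$seed, sc$seed)
  expect_equal(back$scenario$A_true, sc$A_true)
  expect_equal(back$accel_y$samples, rec$accel_y$samples,
               tolerance = 1e-4)
  expect_lt(max(abs(back$speech$samples - rec$speech$samples)), 1e-4)
})

test_that("cohort generation is reproducible and labelled", {
  c1 <- make_cohort(n_controls = 3, n_pd = 2, seed = 11, duration = 2)
  c2 <- make_cohort(n_controls = 3, n_pd = 2, seed = 11, duration = 2)
  expect_identical(c1$id, c2$id)
  expect_identical(c1$scenarios[[4]]$A_true, c2$scenarios[[4]]$A_true)
  expect_equal(sum(c1$cohort == "pd"), 2)
  expect_equal(c1$scenarios[[4]]$hypokinesia, 0.4)
  expect_equal(c1$scenarios[[1]]$hypokinesia, 1)
})
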
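test_that("the mounting angle is recovered from the gravity direction", {
  g <- 981
  n <- 2000
  ax0 <- sampled_trace(rep(0, n), 500); ay0 <- sampled_trace(rep(g, n), 500)
  expect_equal(estimate_rotation(ax0, ay0)$theta_interp,
               rep(0, n), tolerance = 1e-12)
  th <- 10 * pi / 180
  axt <- sampled_trace(rep(g * sin(th), n), 500)
  ayt <- sampled_trace(rep(g * cos(th), n), 500)
  expect_equal(mean(estimate_rotation(axt, ayt)$theta), th,
               tolerance = 0.1 * pi / 180)
  # degenerate free-fall input
  expect_error(estimate_rotation(sampled_trace(rep(0, n), 500),
                                 sampled_trace(rep(0, n), 500)),
               "undefined")
})

test_that("an injected angle is recovered from a noisy moving recording", {
  sc <- articulation_scenario(duration = 4, seed = 6, theta = 0.3)
  rec <- make_recording(sc)
  ax <- resample_antialias(rec$accel_x, 500, 250)
  ay <- resample_antialias(rec$accel_y, 500, 250)
  est <- estimate_rotation(ax, ay)
  expect_equal(mean(est$theta), 0.3, tolerance = 0.02 / 0.3)
})

test_that("rotation is the exact inverse map and an isometry", {
  set.seed(3)
  n <- 1000
  ax <- sampled_trace(rnorm(n), 500); ay <- sampled_trace(rnorm(n), 500)
  # theta = 0 is the identity
  r0 <- rotate_accel(ax, ay, 0)
  expect_equal(r0$a_xd$samples, ax$samples)
  expect_equal(r0$a_yd$samples, ay$samples)
  # norm preserved at every sample for any angle
  r1 <- rotate_accel(ax, ay, 0.7)
  expect_equal(sqrt(r1$a_xd$samples^2 + r1$a_yd$samples^2),
               sqrt(ax$samples^2 + ay$samples^2), tolerance = 1e-12)
  # theta = pi/2 swaps the axes (device x carried gravity-like content)
  a <- sampled_trace(rep(2, n), 500); z <- sampled_trace(rep(0, n), 500)
  r2 <- rotate_accel(a, z, pi / 2)
  expect_equal(r2$a_yd$samples, rep(2, n), tolerance = 1e-12)
  expect_equal(r2$a_xd$samples, rep(0, n), tolerance = 1e-12)
})

test_that("integration yields the closed-form speed of a sinusoidal motion", {
  # zero acceleration -> zero speed
  z <- sampled_trace(rep(0, 2000), 500)
  expect_true(all(integrate_velocity(z, z)$speed == 0))
  # a_y = -Y (2 pi f)^2 sin(2 pi f t): peak speed = 2 pi f Y within 2%
  rate <- 500; Y <- 0.2; f <- 2.5
  t <- seq(0, 8, by = 1 / rate)
  ay <- sampled_trace(-Y * (2 * pi * f)^2 * sin(2 * pi * f * t), rate)
  v <- integrate_velocity(sampled_trace(rep(0, length(t)), rate), ay)
  i <- t > 2 & t < 6
  expect_equal(max(v$speed[i]), 2 * pi * f * Y, tolerance = 0.02)
  # linearity: doubling the input doubles the speed
  ay2 <- sampled_trace(2 * ay$samples, rate)
  v2 <- integrate_velocity(sampled_trace(rep(0, length(t)), rate), ay2)
  expect_equal(v2$speed, 2 * v$speed, tolerance = 1e-9)
  # speed is the per-sample norm
  expect_equal(v$speed, sqrt(v$vx^2 + v$vy^2))
})

test_that("quadratic coefficients reproduce the norm of W times the derivative", {
  expect_equal(quad_coeffs(diag(2)), list(H1 = 1, H2 = 1, H12 = 0))
  expect_equal(quad_coeffs(matrix(c(0, 1, 1, 0), 2, 2)),
               list(H1 = 1, H2 = 1, H12 = 0))
  set.seed(4)
  for (rep in 1:5) {
    W <- matrix(rnorm(4), 2, 2)
    H <- quad_coeffs(W)
    dF <- matrix(rnorm(2000), 2)
    direct <- sqrt(colSums((W %*% dF)^2))
    viaH <- afv(dF[1, ], dF[2, ], H)
    expect_equal(viaH, direct, tolerance = 1e-10)
    # positive semidefinite by construction
    expect_true(H$H12^2 <= 4 * H$H1 * H$H2 + 1e-12)
  }
})

test_that("afv honors its contract on edge inputs", {
  H <- quad_coeffs(diag(2))
  expect_equal(afv(0, 0, H), 0)
  expect_equal(afv(3, 4, H), 5)
  expect_error(afv(1, 1, list(H1 = 1, H2 = 1, H12 = 5)), "semidefinite")
})

test_that("AKV is invariant to the mounting angle within 3% RMS", {
  run_akv <- function(theta) {
    sc <- articulation_scenario(duration = 4, seed = 12, theta = theta,
                                noise_accel = 0, noise_semg = 0)
    rec <- make_recording(sc)
    ax <- resample_antialias(rec$accel_x, 500, 250)
    ay <- resample_antialias(rec$accel_y, 500, 250)
    rot <- estimate_rotation(ax, ay)
    r <- rotate_accel(ax, ay, rot)
    integrate_velocity(detrend(r$a_xd, 0.5), detrend(r$a_yd, 0.5))$speed
  }
  s0 <- run_akv(0)
  s3 <- run_akv(0.3)
  i <- 500:1500
  expect_lt(sqrt(mean((s0[i] - s3[i])^2)) / sqrt(mean(s0[i]^2)), 0.03)
})

test_that("speed distributions are invariant to time reversal", {
  sc <- articulation_scenario(duration = 4, seed = 13)
  rec <- make_recording(sc)
  ax <- resample_antialias(rec$accel_x, 500, 250)
  ay <- resample_antialias(rec$accel_y, 500, 250)
  r <- rotate_accel(ax, ay, estimate_rotation(ax, ay))
  fwd <- integrate_velocity(detrend(r$a_xd, 0.5), detrend(r$a_yd, 0.5))
  rev_in <- integrate_velocity(
    sampled_trace(rev(detrend(r$a_xd, 0.5)$samples), 500),
    sampled_trace(rev(detrend(r$a_yd, 0.5)$samples), 500))
  expect_lt(jsd(velocity_histogram(fwd$speed),
                velocity_histogram(rev_in$speed)), 1e-6)
})

test_that("AFV and AKV distributions agree end to end on a clean recording", {
  ca <- clean_run()
  an <- ca$analysis
  expect_lt(jsd(an$akv_dist$p, an$afv_dist$p), 0.1)
})

test_that("acoustic and dynamic accelerations correlate as in real cohorts", {
  ca <- clean_run()
  expect_gt(ca$analysis$features["r_df"], 0.75)
})
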
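test_that("cross-correlation alignment finds identity, shifts and sign flips", {
  set.seed(41)
  x <- lowpass(rnorm(3000), 500, 40)
  # identity
  al <- xcorr_align(x, x, rate = 500)
  expect_equal(al$lag, 0L)
  expect_equal(al$r_pearson, 1)
  # constructed 16 ms delay at 500 Hz -> exactly 8 samples
  y <- c(rep(0, 8), x[1:(length(x) - 8)])
  al2 <- xcorr_align(x, y, rate = 500)
  expect_equal(al2$lag, 8L)
  expect_equal(al2$lag_ms, 16)
  expect_gt(al2$r_pearson, 0.99)
  # anti-correlated series: lag 0, r = -1 maximizes |r|
  al3 <- xcorr_align(x, -x, rate = 500)
  expect_equal(al3$lag, 0L)
  expect_equal(al3$r_pearson, -1)
  # constant input is rejected
  expect_error(xcorr_align(rep(1, 3000), x, rate = 500), "constant")
})

test_that("lag is antisymmetric under argument exchange", {
  set.seed(42)
  x <- lowpass(rnorm(4000), 500, 30)
  y <- c(rep(0, 5), x[1:(length(x) - 5)])
  expect_equal(xcorr_align(x, y, rate = 500)$lag,
               -xcorr_align(y, x, rate = 500)$lag)
})

test_that("pairwise fits recover constructed slopes and lags", {
  set.seed(43)
  x <- lowpass(rnorm(4000), 500, 30)
  f <- fit_pairwise(x, 2 * x, rate = 500)
  expect_equal(f$lag, 0L)
  expect_equal(f$slope, 2, tolerance = 1e-9)
  expect_equal(f$r_pearson, 1)
  # y = 2 x(t - 2 ms) at 500 Hz: lag one sample, slope 2
  y <- 2 * c(0, x[1:(length(x) - 1)])
  f2 <- fit_pairwise(x, y, rate = 500)
  expect_equal(f2$lag, 1L)
  expect_equal(f2$slope, 2, tolerance = 1e-6)
})

test_that("noiseless aligned regression recovers slopes to near machine precision", {
  set.seed(44)
  dy <- lowpass(rnorm(4000), 500, 10)
  dF1 <- -555 * dy
  dF2 <- 1100 * dy
  pm <- fit_projection(dy, dF1 = dF1, dF2 = dF2, rate = 500,
                       deriv_cutoff = NULL, track_window_ms = NULL)
  expect_equal(unname(pm$table["a21"]), -55.5, tolerance = 1e-6)
  expect_equal(unname(pm$table["a22"]), 110, tolerance = 1e-6)
  expect_equal(pm$r21, -1, tolerance = 1e-9)
  expect_equal(pm$lags_ms, c(f1 = 0, f2 = 0))
})

test_that("uncorrelated displacement yields near-zero gains and correlations", {
  set.seed(45)
  dy <- lowpass(rnorm(4000), 500, 10)
  dF <- lowpass(rnorm(4000), 500, 10)
  pm <- fit_projection(dy, dF1 = dF, dF2 = rev(dF), rate = 500,
                       max_lag_ms = 20,
                       deriv_cutoff = NULL, track_window_ms = NULL)
  expect_lt(abs(pm$r21), 0.2)
  expect_lt(abs(pm$table["a21"]) / 55.5, 0.1)
})

test_that("the full two-column fit satisfies W A = I to machine precision", {
  set.seed(46)
  dy <- lowpass(rnorm(4000), 500, 10)
  dx <- lowpass(rnorm(4000), 500, 10)
  A_true <- matrix(c(111, 220, -555, 1100), 2, 2)
  dF <- A_true %*% rbind(dx, dy)
  pm <- fit_projection(dy, dF1 = dF[1, ], dF2 = dF[2, ], dx = dx,
                       rate = 500, deriv_cutoff = NULL,
                       track_window_ms = NULL)
  expect_false(pm$vertical_only)
  expect_equal(pm$A, A_true, tolerance = 1e-6)
  expect_equal(pm$W %*% pm$A, diag(2), tolerance = 1e-9)
})

test_that("the projection model behaves like a fitted R model object", {
  ca <- clean_run()
  pm <- ca$analysis$projection
  expect_s3_class(pm, "projection_model")
  expect_named(coef(pm), c("a21", "a22"))
  expect_output(print(pm), "a21")
  expect_output(print(summary(pm)), "regression")
  pred <- predict(pm, data.frame(dy = c(0, 0.001)))
  expect_equal(pred$dF1[1], 0)
  expect_equal(pred$dF1[2], pm$gains_hz_cm[["f1"]] * 0.001 +
                 pm$A[1, 1] * 0)
  res <- residuals(pm)
  expect_named(res, c("f1", "f2"))
})

test_that("acoustic accelerations vanish for constant formants and track truth", {
  tr <- structure(list(times = seq(0, 2, by = 0.002),
                       F1 = rep(700, 1001), F2 = rep(1400, 1001),
                       voiced = rep(TRUE, 1001), rate = 500, step = 0.002),
                  class = "formant_track")
  ac <- acoustic_accel(tr, diag(2) * 1e-3)
  expect_lt(max(abs(ac$a_fy$samples)), 1e-6)
  expect_error(acoustic_accel(tr, matrix(0, 2, 2)), "singular")
  # on a clean recording the acoustic vertical acceleration matches truth
  ca <- clean_run()
  rec <- make_recording(ca$scenario)
  an <- ca$analysis
  tru <- approx(rec$truth$t,
                second_diff_for_test(rec$truth$dy, 1 / 2500),
                xout = trace_time(an$acoustic$a_fy))$y
  al <- xcorr_align(an$acoustic$a_fy$samples, lowpass(tru, 500, 15),
                    rate = 500, max_lag_ms = 40)
  expect_gt(abs(al$r_pearson), 0.95)
})

test_that("sign structure matches the universal cohort pattern", {
  ca <- clean_run()
  pm <- ca$analysis$projection
  expect_lt(pm$r21, 0)
  expect_gt(pm$r22, 0)
  expect_lt(sign(pm$table["a21"]), 0)
  expect_gt(sign(pm$table["a22"]), 0)
})
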
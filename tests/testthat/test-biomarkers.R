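test_that("velocity histograms follow the half-open counting rule", {
  # all speeds at 0.5 cm/s land in the single bin [0.4, 0.6)
  vd <- velocity_histogram(rep(0.5, 100))
  expect_equal(sum(vd$p > 0), 1)
  expect_equal(vd$p[3], 1)                       # third bin is [0.4, 0.6)
  expect_equal(diff(vd$bin_edges)[1], 0.2)       # 20 / 100
  expect_equal(length(vd$p), 100)
  # a value exactly on an edge belongs to the upper bin
  vd2 <- velocity_histogram(c(0.4, 0.4))
  expect_equal(which(vd2$p > 0), 3)
  # overflow accumulates in the top bin, conserving probability
  vd3 <- velocity_histogram(c(1, 25, 300))
  expect_equal(sum(vd3$p), 1, tolerance = 1e-12)
  expect_equal(vd3$p[100], 2 / 3)
  expect_error(velocity_histogram(numeric(0)), "empty")
  expect_error(velocity_histogram(c(-1, 2)), "nonnegative")
})

test_that("uniform speeds converge to the flat distribution", {
  set.seed(51)
  vd <- velocity_histogram(runif(1e6, 0, 20))
  expect_true(all(abs(vd$p - 0.01) < 0.002))
  expect_equal(sum(vd$p), 1, tolerance = 1e-12)
})

test_that("KLD matches hand-computed values and the zero-support case", {
  expect_equal(kld(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(kld(c(1, 0), c(0.5, 0.5)), log(2), tolerance = 1e-12)
  expect_identical(kld(c(0.5, 0.5), c(1, 0)), Inf)
  expect_error(kld(c(1, 0), c(0.2, 0.3, 0.5)), "bins")
})

test_that("JSD is symmetric, bounded by log 2 and zero on identity", {
  expect_equal(jsd(c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_equal(jsd(c(1, 0), c(0, 1)), log(2), tolerance = 1e-12)
  set.seed(52)
  for (i in 1:25) {
    p <- runif(100); p <- p / sum(p)
    q <- runif(100); q <- q / sum(q)
    # random zero patterns stay finite through the mixture
    p[sample(100, 20)] <- 0; p <- p / sum(p)
    d1 <- jsd(p, q); d2 <- jsd(q, p)
    expect_equal(d1, d2, tolerance = 1e-12)
    expect_gte(d1, 0)
    expect_lte(d1, log(2) + 1e-12)
    expect_true(is.finite(d1))
  }
})

test_that("the control reference is the per-bin arithmetic mean", {
  d1 <- velocity_histogram(rep(0.5, 10))
  d2 <- velocity_histogram(rep(1.5, 10))
  # single control: reference equals it
  expect_equal(cohort_reference(list(d1))$p_CP, d1$p)
  # two identical controls: reference equals either
  expect_equal(cohort_reference(list(d1, d1))$p_CP, d1$p)
  # disjoint point masses: equal-weight mixture
  ref <- cohort_reference(list(d1, d2))
  expect_equal(sum(ref$p_CP), 1, tolerance = 1e-12)
  expect_equal(ref$p_CP[d1$p > 0], 0.5)
  expect_equal(ref$p_CP[d2$p > 0], 0.5)
  expect_equal(ref$k_C, 2)
  # mixed modalities are rejected
  d3 <- velocity_histogram(rep(0.5, 10), modality = "afv")
  expect_error(cohort_reference(list(d1, d3)), "modalit")
})

test_that("participant scoring returns bounded divergences with identity at zero", {
  set.seed(53)
  dists <- list(a = velocity_histogram(runif(500, 0, 3)),
                b = velocity_histogram(runif(500, 0, 1)),
                c = velocity_histogram(runif(500, 2, 5)))
  ref <- cohort_reference(dists["a"])
  sc <- score_participants(dists, ref)
  expect_equal(sc$jsd[sc$participant_id == "a"], 0, tolerance = 1e-12)
  expect_true(all(sc$jsd >= 0 & sc$jsd <= log(2)))
  # leave-one-out scores a control against the others' mean
  ref2 <- cohort_reference(dists[c("a", "b")])
  sc2 <- score_participants(dists, ref2, leave_one_out = TRUE,
                            control_ids = c("a", "b"),
                            control_distributions = dists[c("a", "b")])
  expect_equal(sc2$jsd[1], jsd(dists$a$p, dists$b$p), tolerance = 1e-12)
})

test_that("hypokinesia shifts velocity mass toward lower bins", {
  run_dist <- function(hypo) {
    sc <- articulation_scenario(duration = 4, seed = 17, hypokinesia = hypo)
    rec <- make_recording(sc)
    ax <- resample_antialias(rec$accel_x, 500, 250)
    ay <- resample_antialias(rec$accel_y, 500, 250)
    r <- rotate_accel(ax, ay, estimate_rotation(ax, ay))
    v <- integrate_velocity(detrend(r$a_xd, 0.5), detrend(r$a_yd, 0.5))
    velocity_histogram(v$speed)
  }
  d_norm <- run_dist(1)
  d_hypo <- run_dist(0.4)
  # stochastic dominance of the cumulative distributions
  expect_true(all(cumsum(d_hypo$p) >= cumsum(d_norm$p) - 1e-12))
  expect_gt(jsd(d_norm$p, d_hypo$p), 0.1)
})

test_that("long-run JSD against a reference is stable across independent runs", {
  run_dist <- function(seed) {
    sc <- articulation_scenario(duration = 8, seed = seed)
    rec <- make_recording(sc)
    ax <- resample_antialias(rec$accel_x, 500, 250)
    ay <- resample_antialias(rec$accel_y, 500, 250)
    r <- rotate_accel(ax, ay, estimate_rotation(ax, ay))
    v <- integrate_velocity(detrend(r$a_xd, 0.5), detrend(r$a_yd, 0.5))
    velocity_histogram(v$speed)
  }
  d1 <- run_dist(61)
  d2 <- run_dist(62)
  expect_lt(jsd(d1$p, d2$p), 0.02)
})
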
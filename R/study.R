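# Crop two traces on a common-rate grid to their overlapping time span.
align_common_grid <- function(x, y) {
  stopifnot(abs(x$rate - y$rate) < 1e-9)
  rate <- x$rate
  t_start <- max(x$t0, y$t0)
  t_end <- min(x$t0 + (length(x$samples) - 1L) / rate,
               y$t0 + (length(y$samples) - 1L) / rate)
  if (t_end <= t_start) stop("traces do not overlap in time", call. = FALSE)
  t_common <- seq(t_start, t_end, by = 1 / rate)
  resamp <- function(tr) {
    sampled_trace(stats::approx(trace_time(tr), tr$samples,
                                xout = t_common, rule = 2)$y,
                  rate, units = tr$units, label = tr$label, t0 = t_start)
  }
  list(x = resamp(x), y = resamp(y))
}

#' Analyze one multimodal recording
#'
#' Runs the full per-participant pipeline: anti-alias resampling (speech
#' to 8 kHz, acceleration and sEMG to 500 Hz), formant tracking and
#' unbiasing, rotation-angle estimation and rotation into the sagittal
#' frame, integration to the absolute kinematic velocity (AKV), the
#' projection-model fit, the absolute formant velocity (AFV) through the
#' fitted inverse map, the ECMF, the three pairwise regressions, and the
#' AKV/AFV amplitude distributions.
#'
#' @param rec A `multimodal_recording` (from [make_recording()] or
#'   [read_recording()]).
#' @param lpc_order LPC order for formant tracking.
#' @param win_ms,step_ms Formant analysis window and step, ms.
#' @param rotation_window Rotation estimation window, s.
#' @param detrend_cutoff Drift-removal high-pass cutoff, Hz.
#' @param deriv_cutoff Low-pass before differentiation, Hz; the default
#'   `"auto"` uses three times the dominant articulatory frequency of the
#'   vertical displacement (clamped to \[4, 15\] Hz), which keeps
#'   essentially all articulatory velocity variance while rejecting
#'   formant-estimation jitter.
#' @param max_lag_ms Cross-correlation lag search half-width, ms.
#' @param v_max,n_bins Velocity histogram geometry (cm/s, count).
#' @return Object of class `articulation_analysis` with fields `track`,
#'   `rotation`, `velocity` (AKV series), `afv_speed`, `ecmf`,
#'   `projection` (the fitted `projection_model`), `pairwise` (sd, sf,
#'   df), `akv_dist`, `afv_dist`, and a 10-element `features` vector
#'   (r21, a21, r22, a22, r_sd, w_sd, r_sf, w_sf, r_df, w_df).
#' @export
analyze_recording <- function(rec, lpc_order = 10, win_ms = 64,
                              step_ms = 2, rotation_window = 0.5,
                              detrend_cutoff = 0.5, deriv_cutoff = "auto",
                              max_lag_ms = 100, v_max = 20, n_bins = 100) {
  stopifnot(inherits(rec, "multimodal_recording"))

  # --- kinematic chain: 500 Hz, rotate, integrate
  ax500 <- resample_antialias(rec$accel_x, 500, 250)
  ay500 <- resample_antialias(rec$accel_y, 500, 250)
  rotation <- estimate_rotation(ax500, ay500, window_s = rotation_window)
  rot <- rotate_accel(ax500, ay500, rotation)
  a_xd <- detrend(rot$a_xd, detrend_cutoff)
  a_yd <- detrend(rot$a_yd, detrend_cutoff)
  velocity <- integrate_velocity(a_xd, a_yd,
                                 detrend_cutoff = detrend_cutoff)
  dy <- detrend(cumtrapz_uniform(velocity$vy, 1 / velocity$rate),
                detrend_cutoff, rate = velocity$rate)
  dy_trace <- sampled_trace(dy, velocity$rate, units = "cm", label = "dy",
                            t0 = a_yd$t0)
  if (identical(deriv_cutoff, "auto"))
    deriv_cutoff <- min(15, max(4, 3 * dominant_freq(dy, velocity$rate)))

  # --- acoustic chain: 8 kHz, formant track, unbiased oscillations
  speech8 <- resample_antialias(rec$speech, 8000, 4000)
  track <- track_formants(speech8, win_ms = win_ms, step_ms = step_ms,
                          order_K = lpc_order)
  track <- unbias(track, detrend_cutoff = detrend_cutoff,
                  deriv_cutoff = deriv_cutoff)

  # --- projection model and AFV through the fitted inverse map
  projection <- fit_projection(dy_trace, track = track,
                               max_lag_ms = max_lag_ms,
                               deriv_cutoff = deriv_cutoff)
  afv_speed <- afv(track$dF1, track$dF2, projection$H)

  # --- sEMG chain
  semg500 <- resample_antialias(rec$semg, 500, 250)
  emg <- ecmf(semg500, detrend_cutoff = detrend_cutoff)
  ecmf_trace <- sampled_trace(emg$f_m, emg$rate, units = "a.u.",
                              label = "ecmf", t0 = semg500$t0)

  # --- acoustic acceleration and the three pairwise regressions
  ac <- acoustic_accel(track, projection$W, rate_out = 500,
                       deriv_cutoff = deriv_cutoff,
                       detrend_cutoff = detrend_cutoff)
  pw <- function(x, y) {
    g <- align_common_grid(x, y)
    fit_pairwise(g$x, g$y, max_lag_ms = max_lag_ms)
  }
  sd_fit <- pw(ecmf_trace, a_yd)
  sf_fit <- pw(ecmf_trace, ac$a_fy)
  df_fit <- pw(a_yd, ac$a_fy)

  features <- c(
    r21 = projection$r21, a21 = unname(projection$table["a21"]),
    r22 = projection$r22, a22 = unname(projection$table["a22"]),
    r_sd = sd_fit$r_pearson, w_sd = sd_fit$slope,
    r_sf = sf_fit$r_pearson, w_sf = sf_fit$slope,
    r_df = df_fit$r_pearson, w_df = df_fit$slope
  )
  structure(
    list(track = track, rotation = rotation, a_yd = a_yd,
         velocity = velocity, dy = dy_trace, afv_speed = afv_speed,
         afv_times = track$times, ecmf = emg, acoustic = ac,
         projection = projection,
         pairwise = list(sd = sd_fit, sf = sf_fit, df = df_fit),
         akv_dist = velocity_histogram(velocity$speed, v_max, n_bins,
                                       modality = "akv"),
         afv_dist = velocity_histogram(afv_speed, v_max, n_bins,
                                       modality = "afv"),
         features = features,
         scenario = rec$scenario),
    class = "articulation_analysis"
  )
}

#' @export
print.articulation_analysis <- function(x, ...) {
  cat("<articulation_analysis>\n")
  print(x$projection)
  cat(sprintf("  pairwise r: sd = %.2f, sf = %.2f, df = %.2f\n",
              x$pairwise$sd$r_pearson, x$pairwise$sf$r_pearson,
              x$pairwise$df$r_pearson))
  cat(sprintf("  AKV peak %.3g cm/s; AFV peak %.3g cm/s\n",
              max(x$velocity$speed), max(x$afv_speed)))
  invisible(x)
}

#' Run the full cohort study
#'
#' Analyzes every participant of a synthetic cohort (or a supplied list of
#' recordings), builds the control-mean AKV and AFV reference
#' distributions, scores every participant by Jensen-Shannon divergence
#' against them, compares the cohorts' scores with t / Kolmogorov-Smirnov
#' / Mann-Whitney tests (after a Lilliefors normality screen), and runs
#' Holm-Bonferroni-corrected feature-wise tests on the 10 regression
#' features. Participants whose pipeline fails are recorded and skipped.
#'
#' @param cohort A `study_cohort` from [make_cohort()], or a list of
#'   `multimodal_recording`s when `ids` and `groups` are given.
#' @param ids,groups Participant ids and cohort labels
#'   (`"control"`/`"pd"`) when `cohort` is a plain recording list.
#' @param verbose Print progress.
#' @param ... Passed to [analyze_recording()].
#' @return Object of class `cohort_report`: `scores` (per participant and
#'   modality), `tests` (per modality p-values), `features` (participants
#'   x 10), `feature_table` (Holm decision table), `normality`,
#'   `analyses`, `failed`.
#' @export
run_study <- function(cohort, ids = NULL, groups = NULL, verbose = FALSE,
                      ...) {
  if (inherits(cohort, "study_cohort")) {
    ids <- cohort$id
    groups <- cohort$cohort
    recs <- cohort$scenarios
    make <- TRUE
  } else {
    stopifnot(is.list(cohort), !is.null(ids), !is.null(groups),
              length(ids) == length(cohort),
              length(groups) == length(cohort))
    recs <- cohort
    make <- FALSE
  }
  if (length(ids) == 0L) stop("empty participant manifest", call. = FALSE)
  if (anyDuplicated(ids)) stop("participant ids must be unique",
                               call. = FALSE)

  analyses <- vector("list", length(ids))
  names(analyses) <- ids
  failed <- character(0)
  for (i in seq_along(ids)) {
    if (verbose) message("analyzing ", ids[i])
    analyses[[i]] <- tryCatch({
      rec <- if (make) make_recording(recs[[i]]) else recs[[i]]
      analyze_recording(rec, ...)
    }, error = function(e) {
      warning("participant ", ids[i], " failed: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (is.null(analyses[[i]])) failed <- c(failed, ids[i])
  }
  ok <- !vapply(analyses, is.null, logical(1))
  ids_ok <- ids[ok]; groups_ok <- groups[ok]
  analyses_ok <- analyses[ok]
  is_control <- groups_ok == "control"
  if (sum(is_control) < 1L)
    stop("no control participant completed the pipeline", call. = FALSE)

  scores <- NULL
  tests <- list()
  normality <- list()
  for (mod in c("akv", "afv")) {
    field <- paste0(mod, "_dist")
    dists <- lapply(analyses_ok, `[[`, field)
    names(dists) <- ids_ok
    ref <- cohort_reference(dists[is_control])
    sc <- score_participants(dists, ref)
    sc$cohort <- groups_ok
    scores <- rbind(scores, sc)
    a <- sc$jsd[is_control]; b <- sc$jsd[!is_control]
    if (length(b) >= 3L) {
      tests[[mod]] <- compare_cohorts(a, b)
      normality[[mod]] <- list(
        control = if (length(a) >= 5) normality_screen(a) else NULL,
        pd = if (length(b) >= 5) normality_screen(b) else NULL
      )
    }
  }

  feat <- as.data.frame(t(vapply(analyses_ok, `[[`,
                                 numeric(10), "features")))
  feat$participant_id <- ids_ok
  feat$cohort <- groups_ok
  feature_table <- NULL
  if (sum(!is_control) >= 3L && sum(is_control) >= 3L) {
    fa <- feat[is_control, 1:10]
    fb <- feat[!is_control, 1:10]
    feature_table <- feature_decision_table(fa, fb)
  }

  structure(
    list(scores = scores, tests = tests, features = feat,
         feature_table = feature_table, normality = normality,
         analyses = analyses_ok, ids = ids_ok, groups = groups_ok,
         failed = failed),
    class = "cohort_report"
  )
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d participants (%d control, %d pd)",
              length(x$ids), sum(x$groups == "control"),
              sum(x$groups == "pd")))
  if (length(x$failed)) cat(sprintf(", %d failed", length(x$failed)))
  cat("\n\nJSD scores vs control-mean reference (nats):\n")
  wide <- stats::reshape(x$scores, idvar = "participant_id",
                         timevar = "modality", direction = "wide",
                         v.names = "jsd")
  names(wide) <- sub("^jsd\\.", "jsd_", names(wide))
  print(wide[, c("participant_id", "cohort", "jsd_akv", "jsd_afv")],
        row.names = FALSE, digits = 3)
  if (length(x$tests)) {
    cat("\nCohort comparison p-values:\n")
    for (mod in names(x$tests)) {
      tt <- x$tests[[mod]]
      cat(sprintf("  %s: t = %.4g, KS = %.4g, MW = %.4g\n",
                  toupper(mod), tt$p_t, tt$p_ks, tt$p_mw))
    }
  }
  invisible(x)
}

#' @export
summary.cohort_report <- function(object, ...) {
  print(object)
  if (!is.null(object$feature_table)) {
    cat("\nFeature-wise tests (Holm-Bonferroni at 0.05):\n")
    print(object$feature_table, row.names = FALSE, digits = 3)
  }
  invisible(object)
}

#' @export
plot.cohort_report <- function(x, ...) {
  graphics::boxplot(jsd ~ cohort + modality, data = x$scores,
                    ylab = "JSD vs control mean (nats)",
                    xlab = "", col = c("lightblue", "salmon"), ...)
  invisible(x)
}

#' Write study reports as CSV files
#'
#' Emits `scores.csv` (participant JSD table), `features.csv` (the 10
#' regression features per participant) and, when available,
#' `feature_tests.csv` (Holm decision table) into a directory.
#'
#' @param report A `cohort_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "cohort_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$scores, file.path(dir, "scores.csv"),
                   row.names = FALSE)
  utils::write.csv(report$features, file.path(dir, "features.csv"),
                   row.names = FALSE)
  if (!is.null(report$feature_table))
    utils::write.csv(report$feature_table,
                     file.path(dir, "feature_tests.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' Estimate the neuromotor-to-kinematic latency by pooled cross-correlation
#'
#' Generates repeated synthetic recordings, computes the ECMF and the
#' rotated, detrended vertical acceleration for each, and pools their
#' cross-correlation profiles before locating the maximum. A single
#' recording's profile carries phase noise from the stochastic sEMG
#' carrier (the peak can wander by a sample); averaging profiles over
#' repeated recordings is the standard repeated-measurement remedy and
#' localizes the peak to one sample.
#'
#' @param n_recordings Number of repeated recordings to pool.
#' @param duration Duration of each recording, s.
#' @param seed Master seed; per-recording seeds derive from it.
#' @param max_lag_ms Lag search half-width, ms.
#' @param scenario_args Named list of overrides passed to
#'   [articulation_scenario()].
#' @return List with `lag` (samples at 500 Hz), `lag_ms`, `lags`
#'   (search grid) and `profile` (pooled correlations).
#' @export
estimate_emg_lag <- function(n_recordings = 8, duration = 8, seed = 1,
                             max_lag_ms = 20, scenario_args = list()) {
  set.seed(seed)
  subs <- sample.int(2^31 - 2, n_recordings)
  grid <- -floor(max_lag_ms / 2):floor(max_lag_ms / 2)
  profs <- vapply(subs, function(s) {
    sc <- do.call(articulation_scenario,
                  c(list(duration = duration, seed = s), scenario_args))
    rec <- make_recording(sc)
    emg <- ecmf(resample_antialias(rec$semg, 500, 250))
    ax <- resample_antialias(rec$accel_x, 500, 250)
    ay <- resample_antialias(rec$accel_y, 500, 250)
    rot <- estimate_rotation(ax, ay)
    a_yd <- detrend(rotate_accel(ax, ay, rot)$a_yd, 0.5)
    x <- emg$f_m
    y <- a_yd$samples
    n <- min(length(x), length(y))
    vapply(grid, function(lag) {
      if (lag >= 0) stats::cor(x[1:(n - lag)], y[(1 + lag):n])
      else stats::cor(x[(1 - lag):n], y[1:(n + lag)])
    }, numeric(1))
  }, numeric(length(grid)))
  pooled <- rowMeans(profs)
  lag <- grid[which.max(pooled)]
  list(lag = lag, lag_ms = 1000 * lag / 500, lags = grid,
       profile = pooled)
}
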
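#' Lilliefors normality screen
#'
#' Kolmogorov-Smirnov test for normality with estimated mean and standard
#' deviation (Lilliefors correction), decided at the 5% level. Requires at
#' least 5 observations; constant samples are degenerate and reported as
#' rejected.
#'
#' @param samples Numeric vector, `n >= 5`.
#' @param alpha Significance level.
#' @return List with `normal_ok` (logical), `statistic`, `p_value`.
#' @export
normality_screen <- function(samples, alpha = 0.05) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 5L)
    stop("need at least 5 observations for the Lilliefors test",
         call. = FALSE)
  if (stats::sd(samples) == 0)
    return(list(normal_ok = FALSE, statistic = NA_real_,
                p_value = 0, degenerate = TRUE))
  lt <- nortest::lillie.test(samples)
  list(normal_ok = lt$p.value >= alpha,
       statistic = unname(lt$statistic),
       p_value = lt$p.value, degenerate = FALSE)
}

#' Two-sample cohort comparison
#'
#' Runs the three standard two-sided tests on two score vectors: Welch's
#' t-test (set `pooled_t = TRUE` for the pooled-variance variant), the
#' two-sample Kolmogorov-Smirnov test, and the Mann-Whitney (Wilcoxon
#' rank-sum) test with the exact small-sample null distribution when both
#' groups have at most 8 untied observations.
#'
#' @param scores_a,scores_b Numeric vectors, each of length >= 3.
#' @param pooled_t Use the pooled-variance t-test.
#' @return List with `p_t`, `p_ks`, `p_mw`.
#' @export
compare_cohorts <- function(scores_a, scores_b, pooled_t = FALSE) {
  stopifnot(length(scores_a) >= 3L, length(scores_b) >= 3L)
  if (stats::sd(c(scores_a, scores_b)) == 0)
    stop("degenerate comparison: all values tied", call. = FALSE)
  p_t <- stats::t.test(scores_a, scores_b,
                       var.equal = pooled_t)$p.value
  p_ks <- suppressWarnings(stats::ks.test(scores_a, scores_b)$p.value)
  exact <- max(length(scores_a), length(scores_b)) <= 8 &&
    !any(duplicated(c(scores_a, scores_b)))
  p_mw <- suppressWarnings(
    stats::wilcox.test(scores_a, scores_b, exact = exact)$p.value)
  list(p_t = p_t, p_ks = p_ks, p_mw = p_mw)
}

#' Holm-Bonferroni step-down correction
#'
#' Sorts the m p-values in ascending order; the adjusted significance
#' level at rank k (1-based) is `alpha / (m - k + 1)`. Hypotheses are
#' rejected sequentially from rank 1 until the first p-value at or above
#' its level; all later ranks are retained (monotone rejection). For
#' m = 10 and alpha = 0.05 the level ladder is 0.0050, 0.0056, 0.0063,
#' 0.0071, 0.0083, 0.0100, 0.0125, 0.0167, 0.0250, 0.0500 (4 decimals).
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param alpha Family-wise significance level.
#' @return Data frame in the input order with `p`, `rank`, `level`
#'   (adjusted level at that p-value's rank), `reject`.
#' @export
holm_bonferroni <- function(p_values, alpha = 0.05) {
  m <- length(p_values)
  stopifnot(m >= 1L)
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  ord <- order(p_values)
  rank <- integer(m); rank[ord] <- seq_len(m)
  level <- alpha / (m - rank + 1)
  reject_sorted <- logical(m)
  for (k in seq_len(m)) {
    if (p_values[ord[k]] < alpha / (m - k + 1)) reject_sorted[k] <- TRUE
    else break
  }
  reject <- logical(m); reject[ord] <- reject_sorted
  data.frame(p = p_values, rank = rank, level = level, reject = reject)
}

#' Feature-wise cohort decision table
#'
#' For each feature (column), compares the two cohorts with
#' [compare_cohorts()] and applies the Holm-Bonferroni correction across
#' features separately for each test family.
#'
#' @param features_a,features_b Data frames (participants x features) for
#'   the two cohorts, sharing column names.
#' @param alpha Family-wise level.
#' @return Data frame with one row per feature: `p_t`, `p_ks`, `p_mw`,
#'   `holm_level_t`, `reject_t`, and likewise for `ks`, `mw`.
#' @export
feature_decision_table <- function(features_a, features_b, alpha = 0.05) {
  stopifnot(identical(names(features_a), names(features_b)))
  res <- lapply(names(features_a), function(nm) {
    compare_cohorts(features_a[[nm]], features_b[[nm]])
  })
  p_t <- vapply(res, `[[`, numeric(1), "p_t")
  p_ks <- vapply(res, `[[`, numeric(1), "p_ks")
  p_mw <- vapply(res, `[[`, numeric(1), "p_mw")
  h_t <- holm_bonferroni(p_t, alpha)
  h_ks <- holm_bonferroni(p_ks, alpha)
  h_mw <- holm_bonferroni(p_mw, alpha)
  data.frame(
    feature = names(features_a),
    p_t = p_t, holm_level_t = h_t$level, reject_t = h_t$reject,
    p_ks = p_ks, holm_level_ks = h_ks$level, reject_ks = h_ks$reject,
    p_mw = p_mw, holm_level_mw = h_mw$level, reject_mw = h_mw$reject,
    stringsAsFactors = FALSE
  )
}
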
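#' Normalized amplitude histogram of an absolute-velocity series
#'
#' Counts speeds into `N` half-open bins `[b_{k-1}, b_k)` of width
#' `v_max / N` over `[0, v_max]` (defaults: 100 bins of 0.2 cm/s over
#' \[0, 20\] cm/s) and normalizes to total count, yielding a discrete
#' probability distribution. Speeds at or above `v_max` are accumulated in
#' the top bin so that probability is conserved.
#'
#' @param speed Nonnegative numeric vector (cm/s), or a `velocity_series`.
#' @param v_max Upper speed limit, cm/s.
#' @param N Number of bins.
#' @param modality Label, `"akv"` or `"afv"` (free text allowed).
#' @return Object of class `velocity_distribution`: `bin_edges` (length
#'   `N + 1`), `p` (length `N`, sums to 1), `n_total`, `modality`.
#' @export
velocity_histogram <- function(speed, v_max = 20, N = 100,
                               modality = "akv") {
  if (inherits(speed, "velocity_series")) speed <- speed$speed
  speed <- speed[is.finite(speed)]
  if (length(speed) == 0L) stop("empty speed series", call. = FALSE)
  if (any(speed < 0)) stop("speeds must be nonnegative", call. = FALSE)
  width <- v_max / N
  idx <- pmin(floor(speed / width) + 1L, N)
  counts <- tabulate(idx, nbins = N)
  structure(
    list(bin_edges = seq(0, v_max, by = width), p = counts / sum(counts),
         n_total = length(speed), modality = modality),
    class = "velocity_distribution"
  )
}

#' @export
print.velocity_distribution <- function(x, ...) {
  nz <- which(x$p > 0)
  cat(sprintf("<velocity_distribution> %s: %d bins of %.3g cm/s, n = %d\n",
              x$modality, length(x$p), diff(x$bin_edges[1:2]), x$n_total))
  cat(sprintf("  support up to %.3g cm/s\n", x$bin_edges[max(nz) + 1L]))
  invisible(x)
}

#' @export
plot.velocity_distribution <- function(x, ...) {
  mids <- x$bin_edges[-1] - diff(x$bin_edges) / 2
  graphics::plot(mids, x$p, type = "h", xlab = "speed (cm/s)",
                 ylab = "probability", main = x$modality, ...)
  invisible(x)
}

check_same_bins <- function(p, q) {
  pp <- if (inherits(p, "velocity_distribution")) p$p else as.numeric(p)
  qq <- if (inherits(q, "velocity_distribution")) q$p else as.numeric(q)
  if (length(pp) != length(qq))
    stop("distributions must share the same bins", call. = FALSE)
  list(p = pp, q = qq)
}

#' Kullback-Leibler divergence
#'
#' Standard nonnegative form `sum(p * log(p / q))` in nats, with the
#' convention `0 * log(0 / q) = 0`. Infinite when `q` has zero mass where
#' `p` does not (never the case inside [jsd()], whose mixture dominates
#' both arguments).
#'
#' @param p,q Probability vectors on identical bins (or
#'   `velocity_distribution`s).
#' @return Divergence in nats (>= 0, possibly `Inf`).
#' @export
kld <- function(p, q) {
  d <- check_same_bins(p, q)
  pos <- d$p > 0
  if (any(d$q[pos] == 0)) return(Inf)
  sum(d$p[pos] * log(d$p[pos] / d$q[pos]))
}

#' Jensen-Shannon divergence
#'
#' `jsd(p, q) = kld(p, m)/2 + kld(q, m)/2` with mixture `m = (p + q)/2`.
#' Symmetric, always finite, and bounded in `[0, log(2)]` nats.
#'
#' @inheritParams kld
#' @return Divergence in nats.
#' @export
jsd <- function(p, q) {
  d <- check_same_bins(p, q)
  m <- (d$p + d$q) / 2
  0.5 * kld(d$p, m) + 0.5 * kld(d$q, m)
}

#' Control-cohort mean reference distribution
#'
#' Arithmetic per-bin mean of the control participants' velocity
#' distributions; normalization is preserved by linearity.
#'
#' @param control_distributions List of `velocity_distribution`s of one
#'   common modality.
#' @return Object of class `cohort_reference`: `p_CP`, `k_C`, `modality`,
#'   `bin_edges`.
#' @export
cohort_reference <- function(control_distributions) {
  stopifnot(length(control_distributions) >= 1L)
  mods <- unique(vapply(control_distributions, `[[`, character(1),
                        "modality"))
  if (length(mods) > 1L)
    stop("mixed modalities in control set: ",
         paste(mods, collapse = ", "), call. = FALSE)
  ps <- vapply(control_distributions, `[[`,
               numeric(length(control_distributions[[1L]]$p)), "p")
  structure(
    list(p_CP = rowMeans(ps), k_C = length(control_distributions),
         modality = mods,
         bin_edges = control_distributions[[1L]]$bin_edges),
    class = "cohort_reference"
  )
}

#' Per-participant divergence scores against the control reference
#'
#' One Jensen-Shannon divergence per participant distribution versus the
#' control-mean reference. Controls are scored against the reference that
#' includes them (no leave-one-out) unless `leave_one_out` is set, in
#' which case each control named in `control_ids` is scored against the
#' mean of the other controls.
#'
#' @param distributions Named list of `velocity_distribution`s
#'   (participant id as name).
#' @param reference A `cohort_reference` of the same modality.
#' @param leave_one_out Score controls against a reference excluding
#'   themselves.
#' @param control_ids Participant ids of the controls (needed for
#'   `leave_one_out`).
#' @param control_distributions The control distributions (needed for
#'   `leave_one_out`).
#' @return Data frame with `participant_id`, `modality`, `jsd` (nats).
#' @export
score_participants <- function(distributions, reference,
                               leave_one_out = FALSE,
                               control_ids = NULL,
                               control_distributions = NULL) {
  stopifnot(inherits(reference, "cohort_reference"))
  ids <- names(distributions)
  if (is.null(ids)) ids <- as.character(seq_along(distributions))
  scores <- vapply(seq_along(distributions), function(i) {
    d <- distributions[[i]]
    if (d$modality != reference$modality)
      stop("modality mismatch for participant ", ids[i], call. = FALSE)
    ref_p <- reference$p_CP
    if (leave_one_out && ids[i] %in% control_ids) {
      others <- control_distributions[control_ids != ids[i]]
      ref_p <- cohort_reference(others)$p_CP
    }
    jsd(d$p, ref_p)
  }, numeric(1))
  data.frame(participant_id = ids, modality = reference$modality,
             jsd = scores, stringsAsFactors = FALSE)
}
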
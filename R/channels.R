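#' Read multichannel CSV recordings
#'
#' Reads a comma-separated file with a mandatory header row. Each non-time
#' column becomes one [sampled_trace]. The sampling rate is inferred from a
#' time column named `t` (seconds) when present, otherwise `rate` must be
#' supplied.
#'
#' @param path Path to a CSV file (UTF-8, `.` decimal separator).
#' @param rate Sampling rate in Hz; required when no `t` column is present.
#' @param units Named character vector mapping column names to unit labels;
#'   unlisted columns get `"dimensionless"`.
#' @param required Character vector of column names that must be present.
#' @return Named list of [sampled_trace] objects, one per data column.
#' @export
read_channels <- function(path, rate = NULL, units = character(),
                          required = character()) {
  df <- tryCatch(
    utils::read.csv(path, header = TRUE, check.names = FALSE),
    error = function(e) stop("cannot parse CSV '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(df) < 1L) stop("empty CSV: ", path, call. = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L)
    stop("missing mandated column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (nm in names(df)) {
    if (!is.numeric(df[[nm]]))
      stop("non-numeric cells in column '", nm, "'", call. = FALSE)
  }
  t0 <- 0
  if ("t" %in% names(df)) {
    tt <- df[["t"]]
    dt <- stats::median(diff(tt))
    if (!is.finite(dt) || dt <= 0)
      stop("time column 't' must be strictly increasing", call. = FALSE)
    rate <- 1 / dt
    t0 <- tt[1L]
    df[["t"]] <- NULL
  }
  if (is.null(rate))
    stop("no time column and no 'rate' supplied", call. = FALSE)
  out <- lapply(names(df), function(nm) {
    u <- if (nm %in% names(units)) units[[nm]] else "dimensionless"
    sampled_trace(df[[nm]], rate, units = u, label = nm, t0 = t0)
  })
  names(out) <- names(df)
  out
}

#' Write traces as a multichannel CSV
#'
#' All traces must share rate and length; a `t` column (seconds) is written
#' first.
#'
#' @param traces Named list of [sampled_trace] objects.
#' @param path Output path.
#' @param digits Significant digits used for printing.
#' @return `path`, invisibly.
#' @export
write_channels <- function(traces, path, digits = 6) {
  stopifnot(length(traces) >= 1L, all(vapply(traces, is_trace, logical(1))))
  n <- length(traces[[1L]]$samples)
  rate <- traces[[1L]]$rate
  for (tr in traces) {
    if (length(tr$samples) != n || abs(tr$rate - rate) > 1e-9)
      stop("all traces must share length and rate", call. = FALSE)
  }
  df <- data.frame(t = signif(trace_time(traces[[1L]]), digits + 3))
  for (nm in names(traces))
    df[[nm]] <- signif(traces[[nm]]$samples, digits)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
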
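#' Cleaning parameters for telemetry preprocessing
#'
#' @param outlier_sd despiking threshold in multiples of the whole-record SD
#'   (default 4): samples outside `mean +/- outlier_sd * SD` are replaced by
#'   the median of the prior hour.
#' @param jump_cutoff threshold on the absolute first difference per minute
#'   (default `1e5`, an intentionally permissive cutoff for near-instantaneous
#'   logger glitches; effectively inert for physiological Celsius data).
#' @param max_gap_min longest missing run (minutes) that is linearly
#'   interpolated (default 10); longer runs are left missing.
#' @param replace_window_min span of the replacement median window, minutes
#'   (default 60).
#' @return A `preprocess_params` list.
#' @export
preprocess_params <- function(outlier_sd = 4, jump_cutoff = 1e5,
                              max_gap_min = 10, replace_window_min = 60) {
  stopifnot(outlier_sd > 0, jump_cutoff > 0, max_gap_min > 0,
            replace_window_min > 0)
  structure(list(outlier_sd = outlier_sd, jump_cutoff = jump_cutoff,
                 max_gap_min = max_gap_min,
                 replace_window_min = as.integer(replace_window_min)),
            class = "preprocess_params")
}

# median of the non-missing working values in the replace_window_min minutes
# preceding index i; falls back to the nearest preceding (then following)
# non-missing value, with a warning for a short leading prefix
replacement_value <- function(x, i, win) {
  lo <- max(1L, i - win)
  prior <- x[lo:(i - 1L)][!is.na(x[lo:(i - 1L)])]
  if (i <= win && length(prior) > 0) {
    warning(sprintf("sample %d has fewer than %d leading samples; using median of available prefix", i, win))
  }
  if (length(prior) > 0) return(stats::median(prior))
  before <- which(!is.na(x[seq_len(i - 1L)]))
  if (length(before) > 0) return(x[max(before)])
  after <- which(!is.na(x)) ; after <- after[after > i]
  if (length(after) > 0) {
    warning(sprintf("no non-missing sample precedes index %d; using nearest following value", i))
    return(x[min(after)])
  }
  stop("no non-missing samples available for replacement")
}

#' Clean a minute-binned temperature series
#'
#' Applies, in order: (1) replacement of samples outside
#' `mean +/- outlier_sd * SD` (statistics computed once over the whole raw
#' record) by the median of the prior hour's non-missing values; (2) the same
#' replacement for samples whose absolute first difference exceeds
#' `jump_cutoff`; (3) linear interpolation of missing runs no longer than
#' `max_gap_min` minutes. Longer missing runs are preserved and counted. The
#' output grid is identical to the input grid.
#'
#' @param series a [temperature_series()].
#' @param params a [preprocess_params()].
#' @return A list with elements `series` (cleaned [temperature_series()]) and
#'   `report`, a `cleaning_report` counting `outliers_replaced`,
#'   `jumps_replaced`, `gaps_interpolated` (runs), `samples_interpolated` and
#'   `long_gaps_left`.
#' @export
clean_series <- function(series, params = preprocess_params()) {
  stopifnot(inherits(series, "temperature_series"),
            inherits(params, "preprocess_params"))
  x <- series$temp_c
  if (all(is.na(x))) stop("all-missing series cannot be cleaned")
  mu <- mean(x, na.rm = TRUE)
  sdev <- stats::sd(x, na.rm = TRUE)
  win <- params$replace_window_min

  # (1) global +/- outlier_sd SD rule; flags fixed from the raw record,
  # replacements drawn from the progressively cleaned values
  out_idx <- which(!is.na(x) & abs(x - mu) > params$outlier_sd * sdev)
  for (i in out_idx) x[i] <- replacement_value(x, i, win)

  # (2) near-instantaneous jumps in the working series
  jump_idx <- integer(0)
  repeat {
    d <- c(0, abs(diff(x)))
    bad <- which(!is.na(d) & d > params$jump_cutoff & !is.na(x))
    bad <- setdiff(bad, jump_idx)
    if (length(bad) == 0) break
    i <- bad[1]
    x[i] <- replacement_value(x, i, win)
    jump_idx <- c(jump_idx, i)
  }

  # (3) linear interpolation of short internal gaps
  na_runs <- rle(is.na(x))
  ends <- cumsum(na_runs$lengths)
  starts <- ends - na_runs$lengths + 1L
  is_gap <- na_runs$values
  internal <- is_gap & starts > 1L & ends < length(x)
  short <- internal & na_runs$lengths <= params$max_gap_min
  filled <- zoo::na.approx(x, na.rm = FALSE, maxgap = params$max_gap_min)
  # na.approx also fills nothing at edges; keep long runs missing as-is
  n_interp_runs <- sum(short)
  n_interp_samples <- sum(na_runs$lengths[short])
  long_left <- sum(is_gap & !short)

  out <- series
  out$temp_c <- as.numeric(filled)
  report <- structure(list(outliers_replaced = length(out_idx),
                           jumps_replaced = length(jump_idx),
                           gaps_interpolated = n_interp_runs,
                           samples_interpolated = n_interp_samples,
                           long_gaps_left = long_left,
                           series_mean = mu, series_sd = sdev),
                      class = "cleaning_report")
  list(series = out, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf("<cleaning_report> outliers %d, jumps %d, gaps interpolated %d (%d samples), long gaps left %d\n",
              x$outliers_replaced, x$jumps_replaced, x$gaps_interpolated,
              x$samples_interpolated, x$long_gaps_left))
  invisible(x)
}

#' Adolescent phase boundaries
#'
#' The analysis window p26-p74 divides into three equal-length phases:
#' early-to-mid puberty (p26-p41), mid-to-late puberty (p42-p58) and late
#' puberty to early adulthood (p59-p74). Postnatal day d spans ages
#' `[d, d + 1)` days, so the phases are the half-open intervals
#' `[26, 42)`, `[42, 59)` and `[59, 75)`.
#'
#' @return Named list of `c(start, end)` day pairs (ends exclusive).
#' @export
phase_boundaries <- function() {
  list(pre_mid = c(26, 42), mid_late = c(42, 59), late_adult = c(59, 75))
}

#' Split a temperature record into the three adolescent phases
#'
#' @param series a [temperature_series()] covering at least p26-p74.
#' @return A list of class `phase_segments` with `temperature_series` elements
#'   `pre_mid`, `mid_late`, `late_adult` partitioning the `[p26, p75)` samples.
#' @export
segment_phases <- function(series) {
  stopifnot(inherits(series, "temperature_series"))
  b <- phase_boundaries()
  lo <- min(series$age_min) / 1440
  hi <- (max(series$age_min) + 1) / 1440
  if (lo > 26 || hi < 75) {
    stop(sprintf("record covers p%.2f-p%.2f but the analysis window requires p26-p74 (missing %s)",
                 lo, hi,
                 paste(c(if (lo > 26) sprintf("p26-p%.2f", lo),
                         if (hi < 75) sprintf("p%.2f-p74", hi)), collapse = " and ")))
  }
  out <- lapply(b, function(w) window_series(series, w[1], w[2]))
  structure(out, class = "phase_segments", boundaries = b)
}
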
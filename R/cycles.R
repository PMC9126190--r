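#' Detect the pubertal fE2 rise
#'
#' Puberty onset is scored as the first day the fE2 level rises more than
#' `sd_multiple` SDs above its starting value, with mean and SD taken over a
#' pre-pubertal baseline window (default p25-p30, which precedes vaginal
#' opening).
#'
#' @param h a [hormone_series()].
#' @param baseline_window `c(from_day, to_day)` inclusive day window for the
#'   baseline statistics; every day in the window must be observed.
#' @param sd_multiple criterion multiple (default 2).
#' @return A list of class `rise_detection`: `baseline_mean`, `baseline_sd`,
#'   `threshold`, `rise_day` (first qualifying day after the window, `NA` if
#'   none) and `threshold_undefined` (TRUE when the baseline SD is zero and no
#'   day qualifies).
#' @export
detect_rise <- function(h, baseline_window = c(25, 30), sd_multiple = 2) {
  stopifnot(inherits(h, "hormone_series"))
  base_days <- seq.int(baseline_window[1], baseline_window[2])
  if (!all(base_days %in% h$day)) {
    stop(sprintf("baseline window p%d-p%d not fully observed",
                 baseline_window[1], baseline_window[2]))
  }
  base <- h$fe2[h$day %in% base_days]
  mu <- mean(base); sdev <- stats::sd(base)
  thr <- mu + sd_multiple * sdev
  post <- h[h$day > baseline_window[2], , drop = FALSE]
  hit <- which(post$fe2 > thr)
  rise_day <- if (length(hit)) as.integer(post$day[hit[1]]) else NA_integer_
  structure(list(baseline_window = baseline_window, baseline_mean = mu,
                 baseline_sd = sdev, sd_multiple = sd_multiple,
                 threshold = thr, rise_day = rise_day,
                 threshold_undefined = sdev == 0 && is.na(rise_day)),
            class = "rise_detection")
}

#' @export
print.rise_detection <- function(x, ...) {
  cat(sprintf("<rise_detection> baseline p%d-p%d: mean %.2f, sd %.2f, threshold %.2f; rise day %s%s\n",
              x$baseline_window[1], x$baseline_window[2], x$baseline_mean,
              x$baseline_sd, x$threshold,
              if (is.na(x$rise_day)) "none" else paste0("p", x$rise_day),
              if (isTRUE(x$threshold_undefined)) " (threshold undefined: zero baseline SD)" else ""))
  invisible(x)
}

#' Align estrous cycles into day-of-cycle blocks
#'
#' From the detected rise day, days are grouped into consecutive `block_len`
#' day blocks labeled 1..`block_len`. The anchor is shifted (mod `block_len`)
#' so the within-block fE2 maximum sits at index 3, matching a cycle that
#' rises over three days and falls on the fourth. Labels propagate
#' arithmetically through unobserved spans, so non-contiguous collection
#' blocks stay aligned. Ties among equal within-block maxima go to the
#' earliest day.
#'
#' @param h a [hormone_series()].
#' @param rise a `rise_detection` from [detect_rise()], or a plain postnatal
#'   day to anchor on directly (e.g. for non-cycling controls).
#' @param block_len cycle length in days (default 4; 5 only as a sensitivity
#'   analysis).
#' @return A list of class `cycle_alignment`: `anchor_day`, `block_len`,
#'   `peak_day_index` (modal within-block index of the fE2 maximum over
#'   complete blocks), `rise_day` and `labels`, a data frame with one row per
#'   observed day >= the anchor (`day`, `day_of_cycle`, `block`, `complete`).
#' @export
align_cycles <- function(h, rise, block_len = 4) {
  stopifnot(inherits(h, "hormone_series"), block_len >= 2)
  block_len <- as.integer(block_len)
  rise_day <- if (inherits(rise, "rise_detection")) rise$rise_day else as.integer(rise)
  if (is.na(rise_day)) stop("no rise day: cannot align cycles")
  post <- h[h$day >= rise_day, , drop = FALSE]
  if (nrow(post) < block_len) stop("fewer observed days after the rise than one block")

  # phase of maximal mean fE2 relative to the rise day
  ph <- ((post$day - rise_day) %% block_len) + 1L
  phase_mean <- tapply(post$fe2, ph, mean)
  m <- as.integer(names(phase_mean)[which.max(phase_mean)])
  anchor <- rise_day + ((m - 3L) %% block_len)

  lab_days <- post$day                           # label every observed post-rise day
  doc <- ((lab_days - anchor) %% block_len) + 1L
  blk <- floor((lab_days - anchor) / block_len)
  labels <- data.frame(day = lab_days, day_of_cycle = doc, block = blk)
  blk_n <- table(labels$block)
  labels$complete <- blk_n[as.character(labels$block)] == block_len

  peak_idx <- NA_integer_
  cb <- unique(labels$block[labels$complete & labels$block >= 0])
  if (length(cb)) {
    per_block <- vapply(cb, function(b) {
      rows <- labels$block == b
      labels$day_of_cycle[rows][which.max(post$fe2[match(labels$day[rows], post$day)])]
    }, integer(1))
    tab <- table(per_block)
    peak_idx <- as.integer(names(tab)[which.max(tab)])
  }
  structure(list(anchor_day = anchor, block_len = as.integer(block_len),
                 peak_day_index = peak_idx, rise_day = rise_day,
                 labels = labels),
            class = "cycle_alignment")
}

#' @export
print.cycle_alignment <- function(x, ...) {
  n_complete <- length(unique(x$labels$block[x$labels$complete & x$labels$block >= 0]))
  cat(sprintf("<cycle_alignment> rise p%d, anchor p%d, %d-day blocks: %d complete, fE2 peak at day-of-cycle %s\n",
              x$rise_day, x$anchor_day, x$block_len, n_complete,
              if (is.na(x$peak_day_index)) "NA" else x$peak_day_index))
  invisible(x)
}

#' Combined ovulatory metric: z(CBT) - z(UR power)
#'
#' Daily mean CBT and daily ultradian band power are each z-scored per animal
#' over the analysis span and subtracted. The combined metric is high when
#' temperature is elevated and ultradian power suppressed, the signature of
#' the post-fE2-rise cycle day, and is invariant to affine rescaling of either
#' input.
#'
#' @param daily data frame with columns `day`, `cbt_mean`, `ur_power` on a
#'   common day grid (rows with either value missing are dropped).
#' @return data frame with columns `day`, `z_cbt`, `z_ur`, `combined`.
#' @export
combined_metric <- function(daily) {
  stopifnot(is.data.frame(daily),
            all(c("day", "cbt_mean", "ur_power") %in% names(daily)))
  d <- daily[stats::complete.cases(daily[, c("day", "cbt_mean", "ur_power")]), ]
  if (nrow(d) < 2) stop("need at least two complete days")
  zs <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) stop("zero variance in a combined-metric input")
    (x - mean(x)) / s
  }
  data.frame(day = d$day, z_cbt = zs(d$cbt_mean), z_ur = zs(d$ur_power),
             combined = zs(d$cbt_mean) - zs(d$ur_power))
}

#' Build the blocks-by-day-of-cycle matrix for a metric
#'
#' @param values data frame with columns `day`, `value`.
#' @param align a `cycle_alignment`.
#' @return Numeric matrix, one row per complete block, `block_len` columns
#'   (day-of-cycle 1..block_len); incomplete blocks (including blocks with a
#'   missing metric value) are dropped.
#' @export
day_of_cycle_matrix <- function(values, align) {
  stopifnot(inherits(align, "cycle_alignment"),
            all(c("day", "value") %in% names(values)))
  lab <- align$labels[align$labels$block >= 0, ]
  lab$value <- values$value[match(lab$day, values$day)]
  keep_blocks <- vapply(split(lab, lab$block),
                        function(b) nrow(b) == align$block_len && !anyNA(b$value),
                        logical(1))
  blocks <- names(keep_blocks)[keep_blocks]
  if (length(blocks) == 0) return(matrix(numeric(0), 0, align$block_len))
  m <- t(vapply(blocks, function(b) {
    rows <- lab[lab$block == as.integer(b), ]
    rows$value[order(rows$day_of_cycle)]
  }, numeric(align$block_len)))
  colnames(m) <- paste0("doc", seq_len(align$block_len))
  m
}

#' Day-of-cycle test of a daily metric
#'
#' Groups all day-1 values, day-2 values, and so on across aligned complete
#' blocks (each cycle treated as an independent replicate) and tests whether
#' the metric varies by day of cycle with a Friedman omnibus test followed by
#' Dunn's pairwise comparisons.
#'
#' @param x either a data frame with columns `day`, `value` (then `align` is
#'   required) or a pre-built blocks-by-day matrix, e.g. from
#'   [day_of_cycle_matrix()] rows pooled across animals.
#' @param align a `cycle_alignment` (ignored when `x` is a matrix).
#' @param alpha significance level gating the post hoc comparisons.
#' @return A `comparison_result` from [omnibus_with_dunn()], with the block
#'   matrix attached as attribute `"blocks"`.
#' @export
day_of_cycle_test <- function(x, align = NULL, alpha = 0.05) {
  m <- if (is.matrix(x)) x else day_of_cycle_matrix(x, align)
  if (nrow(m) < 2) stop("need at least two complete blocks")
  res <- omnibus_with_dunn(m, design = "repeated", alpha = alpha)
  attr(res, "blocks") <- m
  res
}

# one-sided magnitude spectrum of a linearly detrended daily series
daily_spectrum <- function(values) {
  y <- stats::residuals(stats::lm(values ~ seq_along(values)))
  n <- length(y)
  k <- seq_len(floor(n / 2))
  data.frame(freq = k / n, mag = 2 * Mod(stats::fft(y))[k + 1] / n)
}

#' Spectral area in a multi-day period band
#'
#' Computes the one-sided magnitude spectrum of a linearly detrended daily CBT
#' series and integrates it (trapezoid rule, with linear interpolation at the
#' band edges) over frequencies between `1/band_days[2]` and
#' `1/band_days[1]` cycles/day. Used to score the presence of 4-5 day
#' (estrous) oscillations per animal.
#'
#' @param values numeric vector of daily values (e.g. daily mean CBT), or a
#'   data frame with columns `day`, `value`.
#' @param band_days `c(lo, hi)` period band in days (default `c(4, 5)`).
#' @return Non-negative spectral area (magnitude x cycles/day).
#' @export
fft_band_auc <- function(values, band_days = c(4, 5)) {
  if (is.data.frame(values)) values <- values$value
  if (length(values) < 3 * band_days[2]) {
    stop(sprintf("span of %d days is too short to resolve %g-day periods",
                 length(values), band_days[2]))
  }
  sp <- daily_spectrum(values)
  f_lo <- 1 / band_days[2]; f_hi <- 1 / band_days[1]
  grid <- sort(unique(c(f_lo, f_hi, sp$freq[sp$freq > f_lo & sp$freq < f_hi])))
  mag <- stats::approx(sp$freq, sp$mag, xout = grid, rule = 2)$y
  pracma::trapz(grid, mag)
}

#' Dominant multi-day spectral period
#'
#' @param values numeric vector of daily values, or a data frame with columns
#'   `day`, `value`.
#' @param range_days `c(lo, hi)` period range searched, days.
#' @return Period (days) of the largest non-DC spectral magnitude inside the
#'   range.
#' @export
fft_peak_period <- function(values, range_days = c(3, 6)) {
  if (is.data.frame(values)) values <- values$value
  sp <- daily_spectrum(values)
  per <- 1 / sp$freq
  inside <- per >= range_days[1] & per <= range_days[2]
  if (!any(inside)) stop("no spectral estimates inside the period range")
  per[inside][which.max(sp$mag[inside])]
}

#' Per-cycle fE2 area under the curve
#'
#' Trapezoidal area of fE2 over each complete aligned block (day-unit
#' spacing).
#'
#' @param h a [hormone_series()].
#' @param align a `cycle_alignment` for the same animal.
#' @return data frame with columns `block`, `auc`, one row per complete block.
#' @export
fe2_cycle_auc <- function(h, align) {
  stopifnot(inherits(h, "hormone_series"), inherits(align, "cycle_alignment"))
  m <- day_of_cycle_matrix(data.frame(day = h$day, value = h$fe2), align)
  if (nrow(m) == 0) stop("no complete blocks")
  data.frame(block = as.integer(rownames(m)),
             auc = apply(m, 1, function(v) pracma::trapz(seq_along(v), v)),
             row.names = NULL)
}
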
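#' Morse continuous wavelet transform parameters
#'
#' Generalized Morse wavelets form a two-parameter analytic family; `gamma`
#' controls envelope symmetry and `beta` the number of oscillations
#' (time-frequency compactness). The defaults (`beta = 5`, `gamma = 3`) give a
#' low-oscillation wavelet well suited to slowly modulated physiological
#' rhythms; the analysis is insensitive to moderate changes of either.
#'
#' @param beta Morse beta > 0 (default 5).
#' @param gamma Morse gamma > 0 (default 3).
#' @param period_min_h,period_max_h period range analyzed, hours (default
#'   1-39 h, spanning ultradian through circadian bands).
#' @param voices_per_octave scales per octave of the logarithmic period grid
#'   (default 16, >= 4).
#' @param edge_policy `"cone_of_influence"` marks samples closer to a record
#'   edge than one full period as edge-affected; `"fixed_trim"` marks the
#'   first and last day instead.
#' @return A `wavelet_params` list.
#' @export
wavelet_params <- function(beta = 5, gamma = 3, period_min_h = 1,
                           period_max_h = 39, voices_per_octave = 16,
                           edge_policy = c("cone_of_influence", "fixed_trim")) {
  stopifnot(beta > 0, gamma > 0, period_min_h < period_max_h,
            voices_per_octave >= 4)
  structure(list(beta = beta, gamma = gamma,
                 period_min_h = period_min_h, period_max_h = period_max_h,
                 voices_per_octave = as.integer(voices_per_octave),
                 edge_policy = match.arg(edge_policy)),
            class = "wavelet_params")
}

#' Morse wavelet peak frequency
#'
#' The generalized Morse wavelet's frequency-domain form `omega^beta *
#' exp(-omega^gamma)` peaks at `omega = (beta/gamma)^(1/gamma)` (radian
#' frequency at unit scale). This mapping converts scales to the periods at
#' which a pure tone of that period draws the maximal response.
#'
#' @param beta,gamma Morse parameters.
#' @return Peak radian frequency, unit scale.
#' @export
morse_peak_frequency <- function(beta, gamma) (beta / gamma)^(1 / gamma)

# frequency-domain Morse wavelet, bandpass-normalized so the peak value is 2:
# an analytic wavelet with peak 2 returns |W| = A for a tone of amplitude A
morse_fourier <- function(omega, beta, gamma) {
  a <- 2 * exp(beta / gamma) * (gamma / beta)^(beta / gamma)
  psi <- numeric(length(omega))
  pos <- omega > 0
  psi[pos] <- a * omega[pos]^beta * exp(-omega[pos]^gamma)
  psi
}

# logarithmic period grid, hours
period_grid <- function(params) {
  lo <- log2(params$period_min_h)
  hi <- log2(params$period_max_h)
  p <- 2^seq(lo, hi, by = 1 / params$voices_per_octave)
  if (max(p) < params$period_max_h) p <- c(p, params$period_max_h)
  p
}

#' Morse continuous wavelet transform of a temperature series
#'
#' Computes the analytic generalized Morse CWT in the frequency domain over a
#' logarithmic period grid, returning squared coefficient magnitudes (power)
#' per time sample and period. The series must be gap-free on the 1-minute
#' grid (run [clean_series()] first). The mean is removed before transforming.
#' Samples closer to either record edge than the local cone of influence (one
#' full period by default) are flagged invalid in the `valid` mask.
#'
#' @param series a gap-free [temperature_series()].
#' @param params a [wavelet_params()].
#' @return A list of class `wavelet_spectrum` with `periods_h` (period grid,
#'   hours), `times_min` (sample ages, minutes), `power` (time x period
#'   matrix, >= 0), `valid` (logical matrix, same shape) and `params`.
#' @export
morse_transform <- function(series, params = wavelet_params()) {
  stopifnot(inherits(series, "temperature_series"),
            inherits(params, "wavelet_params"))
  x <- series$temp_c
  n <- length(x)
  if (anyNA(x)) stop("series contains missing values; clean/interpolate before transforming")
  if (n < 2 * params$period_max_h * 60) {
    stop(sprintf("series (%d min) shorter than twice the longest period (%g h)",
                 n, params$period_max_h))
  }
  periods <- period_grid(params)
  per_min <- periods * 60                       # periods in samples (minutes)
  wc <- morse_peak_frequency(params$beta, params$gamma)
  scales <- per_min * wc / (2 * pi)

  # pad by the longest wavelet support so the transform is non-circular,
  # rounded up to a highly composite FFT length
  m <- stats::nextn(n + 2 * ceiling(max(per_min)), c(2, 3, 5))
  xf <- stats::fft(c(x - mean(x), rep(0, m - n)))
  omega <- 2 * pi * (0:(m - 1)) / m
  omega[omega > pi] <- 0                        # analytic: keep positive freqs

  power <- matrix(0, nrow = n, ncol = length(periods))
  for (j in seq_along(scales)) {
    psi <- morse_fourier(scales[j] * omega, params$beta, params$gamma)
    w <- stats::fft(xf * psi, inverse = TRUE)[seq_len(n)] / m
    power[, j] <- Mod(w)^2
  }

  t_rel <- seq_len(n) - 1                       # minutes from record start
  if (params$edge_policy == "cone_of_influence") {
    coi <- outer(pmin(t_rel, n - 1 - t_rel), per_min, `>=`)
  } else {
    coi <- matrix(t_rel >= 1440 & t_rel <= n - 1 - 1440,
                  nrow = n, ncol = length(periods))
  }
  structure(list(periods_h = periods, times_min = series$age_min,
                 power = power, valid = coi, params = params,
                 animal_id = series$animal_id[1]),
            class = "wavelet_spectrum")
}

#' @export
print.wavelet_spectrum <- function(x, ...) {
  cat(sprintf("<wavelet_spectrum> %d samples x %d periods (%.2g-%.2g h), beta=%g gamma=%g\n",
              nrow(x$power), ncol(x$power), min(x$periods_h), max(x$periods_h),
              x$params$beta, x$params$gamma))
  invisible(x)
}

#' Band-maximum wavelet power
#'
#' Per time sample, the maximum wavelet power over grid periods inside
#' `band`. The circadian series uses band `c(23, 25)` hours and the ultradian
#' series `c(1, 3)` hours.
#'
#' @param spec a `wavelet_spectrum` from [morse_transform()].
#' @param band `c(lo_h, hi_h)` period band, hours; must intersect the grid.
#' @return A list of class `band_power_series` with `times_min`, `values`
#'   (max power per minute), `valid` (all band periods edge-clean), `band`.
#' @export
band_max_power <- function(spec, band) {
  stopifnot(inherits(spec, "wavelet_spectrum"), length(band) == 2, band[1] < band[2])
  cols <- which(spec$periods_h >= band[1] & spec$periods_h <= band[2])
  if (length(cols) == 0) stop(sprintf("no grid periods inside band [%g, %g] h", band[1], band[2]))
  pw <- spec$power[, cols, drop = FALSE]
  values <- do.call(pmax, as.data.frame(pw))
  valid <- rowSums(!spec$valid[, cols, drop = FALSE]) == 0
  structure(list(times_min = spec$times_min, values = values, valid = valid,
                 band = band, smoothed = FALSE, normalized = FALSE,
                 animal_id = spec$animal_id),
            class = "band_power_series")
}

#' @export
print.band_power_series <- function(x, ...) {
  cat(sprintf("<band_power_series> band [%g, %g] h, %d samples%s%s\n",
              x$band[1], x$band[2], length(x$values),
              if (x$smoothed) ", smoothed" else "",
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Moving-mean smoothing of a band power series
#'
#' Centered moving mean with the window truncated at the record edges;
#' edge-invalid samples are excluded from every window mean.
#'
#' @param bp a `band_power_series`.
#' @param window_h smoothing window, hours (default 24).
#' @return The smoothed `band_power_series`.
#' @export
smooth_power <- function(bp, window_h = 24) {
  stopifnot(inherits(bp, "band_power_series"))
  w <- round(window_h * 60)
  if (w < 2) stop("window must span at least 2 samples")
  if (!any(bp$valid)) stop("all samples are edge-invalid")
  x <- ifelse(bp$valid, bp$values, NA_real_)
  n <- length(x)
  cx <- cumsum(ifelse(is.na(x), 0, x))
  ck <- cumsum(!is.na(x))
  lo <- pmax(seq_len(n) - (w - 1L) %/% 2, 1L)     # exactly w samples when interior
  hi <- pmin(seq_len(n) + w %/% 2, n)
  s <- cx[hi] - c(0, cx)[lo]
  k <- ck[hi] - c(0, ck)[lo]
  out <- bp
  out$values <- ifelse(k > 0, s / k, NA_real_)
  out$smoothed <- TRUE
  out
}

#' Z-score normalization of a band power series over a reference interval
#'
#' @param bp a `band_power_series`.
#' @param reference `c(from_day, to_day)` postnatal-day interval supplying the
#'   mean and SD (default: the whole record).
#' @return The normalized `band_power_series` (values may be negative).
#' @export
normalize_power <- function(bp, reference = NULL) {
  stopifnot(inherits(bp, "band_power_series"))
  day <- bp$times_min / 1440
  if (is.null(reference)) reference <- c(min(day), max(day) + 1 / 1440)
  if (reference[1] >= reference[2]) stop("degenerate reference interval")
  ref <- day >= reference[1] & day < reference[2] & bp$valid & !is.na(bp$values)
  if (!any(ref)) stop("reference interval contains no valid samples")
  mu <- mean(bp$values[ref])
  sdev <- stats::sd(bp$values[ref])
  if (!is.finite(sdev) || sdev == 0) stop("zero SD over the reference interval")
  out <- bp
  out$values <- (bp$values - mu) / sdev
  out$normalized <- TRUE
  out
}

#' Daily summary of a band power series
#'
#' Aggregates a minute-resolution band power series to one value per postnatal
#' day over edge-valid samples (the paper-style daily statistic is the
#' median).
#'
#' @param bp a `band_power_series`.
#' @param fun summary function (default `median`).
#' @return data frame with columns `day`, `value`.
#' @export
daily_band_stat <- function(bp, fun = stats::median) {
  keep <- bp$valid & !is.na(bp$values)
  day <- floor(bp$times_min[keep] / 1440)
  v <- tapply(bp$values[keep], day, fun)
  data.frame(day = as.integer(names(v)), value = as.numeric(v), row.names = NULL)
}

#' First crossing of a 2-SD power criterion
#'
#' Finds the first postnatal day at which a daily-resolution power series
#' exceeds `mean + sd_multiple * SD` of the series over a reference day
#' window. Used to compare the rate of the early-adolescent circadian power
#' rise between groups.
#'
#' @param daily data frame with columns `day`, `value` (daily band power,
#'   typically medians of the 24 h-smoothed circadian series).
#' @param reference `c(from_day, to_day)` days defining the baseline (half
#'   open, end exclusive).
#' @param sd_multiple criterion multiple (default 2).
#' @return The first qualifying day, or `NA` if the criterion is never met.
#' @export
crossing_time <- function(daily, reference, sd_multiple = 2) {
  stopifnot(is.data.frame(daily), all(c("day", "value") %in% names(daily)),
            sd_multiple > 0)
  ref <- daily$day >= reference[1] & daily$day < reference[2]
  if (!any(ref)) stop("reference window lies outside the record")
  thr <- mean(daily$value[ref]) + sd_multiple * stats::sd(daily$value[ref])
  after <- daily[daily$day >= reference[2], , drop = FALSE]
  hit <- which(after$value > thr)
  if (length(hit) == 0) return(NA_integer_)
  as.integer(after$day[hit[1]])
}
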
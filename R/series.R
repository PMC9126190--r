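#' Minute-binned core body temperature series
#'
#' Container for one animal's continuous core body temperature (CBT) record on
#' a uniform 1-minute grid. Age is carried in minutes of postnatal life so the
#' grid is exactly integer-spaced; use [age_days()] for the day axis. Missing
#' samples are explicit `NA`s, never dropped rows.
#'
#' @param animal_id single identifier string.
#' @param age_min integer vector of postnatal age in minutes, strictly
#'   increasing with unit spacing.
#' @param temp_c numeric vector of temperatures in degrees Celsius, same length
#'   as `age_min`; `NA` marks a missing sample.
#' @return A `temperature_series` object (a data frame with columns
#'   `animal_id`, `age_min`, `temp_c`).
#' @examples
#' ts <- temperature_series("r1", age_min = seq(25 * 1440, length.out = 120),
#'                          temp_c = rnorm(120, 37, 0.1))
#' range(age_days(ts))
#' @export
temperature_series <- function(animal_id, age_min, temp_c) {
  stopifnot(length(animal_id) == 1L, length(age_min) == length(temp_c))
  if (length(age_min) == 0L) stop("empty temperature series")
  age_min <- as.double(age_min)
  if (any(diff(age_min) != 1)) {
    stop("age_min must be strictly increasing on a 1-minute grid")
  }
  out <- data.frame(animal_id = as.character(animal_id),
                    age_min = age_min,
                    temp_c = as.double(temp_c))
  class(out) <- c("temperature_series", "data.frame")
  out
}

#' Postnatal age in (fractional) days
#'
#' @param x a `temperature_series`.
#' @return numeric vector, `age_min / 1440`.
#' @export
age_days <- function(x) x$age_min / 1440

#' @export
print.temperature_series <- function(x, ...) {
  d <- range(x$age_min) / 1440
  cat(sprintf("<temperature_series> animal %s: %d samples, p%.2f-p%.2f, %d missing\n",
              x$animal_id[1], nrow(x), d[1], d[2], sum(is.na(x$temp_c))))
  invisible(x)
}

#' Daily fecal estradiol series
#'
#' One fE2 assay value per postnatal day for one animal. Collection blocks may
#' be non-contiguous; days must be strictly increasing.
#'
#' @param animal_id single identifier string.
#' @param day integer vector of postnatal days, strictly increasing.
#' @param fe2 non-negative fE2 concentrations (pg/ml), same length as `day`.
#' @return A `hormone_series` object (a data frame with columns `animal_id`,
#'   `day`, `fe2`).
#' @export
hormone_series <- function(animal_id, day, fe2) {
  stopifnot(length(animal_id) == 1L, length(day) == length(fe2))
  if (length(day) == 0L) stop("empty hormone series")
  if (any(diff(day) <= 0)) stop("days must be strictly increasing")
  if (any(fe2 < 0, na.rm = TRUE)) stop("fe2 must be non-negative")
  out <- data.frame(animal_id = as.character(animal_id),
                    day = as.integer(day),
                    fe2 = as.double(fe2))
  class(out) <- c("hormone_series", "data.frame")
  out
}

#' @export
print.hormone_series <- function(x, ...) {
  cat(sprintf("<hormone_series> animal %s: %d days, p%d-p%d\n",
              x$animal_id[1], nrow(x), min(x$day), max(x$day)))
  invisible(x)
}

# subset a temperature series to an age window [from_day, to_day) keeping class
window_series <- function(ts, from_day, to_day) {
  keep <- ts$age_min >= from_day * 1440 & ts$age_min < to_day * 1440
  out <- ts[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(ts)
  out
}
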
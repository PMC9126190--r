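#' Read a minute-binned temperature CSV
#'
#' Expects columns `animal_id`, `age_min` (integer postnatal minutes) or
#' `age_days`, and `temp_c`. Rows must be unique and increasing in time per
#' animal; minutes absent from the file become explicit missing samples so the
#' returned series sit on a complete 1-minute grid.
#'
#' @param path CSV file path.
#' @return Named list of [temperature_series()], one per animal.
#' @export
read_temperature_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"age_min" %in% names(df)) {
    if (!"age_days" %in% names(df)) stop("need an age_min or age_days column")
    df$age_min <- round(df$age_days * 1440)
  }
  if (!all(c("animal_id", "temp_c") %in% names(df))) {
    stop("need animal_id and temp_c columns")
  }
  out <- lapply(split(df, df$animal_id), function(d) {
    dup <- duplicated(d$age_min)
    if (any(dup)) {
      stop(sprintf("duplicate timestamp for animal %s at age_min %s (file row %s)",
                   d$animal_id[1], d$age_min[which(dup)[1]],
                   rownames(d)[which(dup)[1]]))
    }
    if (is.unsorted(d$age_min)) {
      stop(sprintf("non-monotone time for animal %s", d$animal_id[1]))
    }
    grid <- seq.int(min(d$age_min), max(d$age_min))
    temp <- rep(NA_real_, length(grid))
    temp[match(d$age_min, grid)] <- d$temp_c
    temperature_series(d$animal_id[1], grid, temp)
  })
  out[order(names(out))]
}

#' Write temperature series to CSV
#'
#' Inverse of [read_temperature_csv()]; missing samples are written as empty
#' fields so a round trip reproduces the series exactly.
#'
#' @param series_list a [temperature_series()] or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_temperature_csv <- function(series_list, path) {
  if (inherits(series_list, "temperature_series")) series_list <- list(series_list)
  df <- do.call(rbind, lapply(series_list, function(s)
    data.frame(animal_id = s$animal_id, age_min = s$age_min, temp_c = s$temp_c)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a daily hormone CSV
#'
#' Expects columns `animal_id`, `day`, `fe2`.
#'
#' @param path CSV file path.
#' @return Named list of [hormone_series()], one per animal.
#' @export
read_hormone_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("animal_id", "day", "fe2") %in% names(df))) {
    stop("need animal_id, day and fe2 columns")
  }
  out <- lapply(split(df, df$animal_id), function(d) {
    dup <- duplicated(d$day)
    if (any(dup)) stop(sprintf("duplicate day for animal %s at day %d",
                               d$animal_id[1], d$day[which(dup)[1]]))
    if (is.unsorted(d$day)) stop(sprintf("non-monotone days for animal %s", d$animal_id[1]))
    hormone_series(d$animal_id[1], d$day, d$fe2)
  })
  out[order(names(out))]
}

#' Write hormone series to CSV
#'
#' @param series_list a [hormone_series()] or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_hormone_csv <- function(series_list, path) {
  if (inherits(series_list, "hormone_series")) series_list <- list(series_list)
  df <- do.call(rbind, lapply(series_list, function(s)
    data.frame(animal_id = s$animal_id, day = s$day, fe2 = s$fe2)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write a synthetic cohort to CSV files with a ground-truth sidecar
#'
#' @param bundle a `cohort_bundle` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return Named vector of written file paths, invisibly.
#' @export
write_cohort_csv <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(temperature = file.path(dir, "temperature.csv"),
             hormone = file.path(dir, "hormone.csv"),
             design = file.path(dir, "design.csv"),
             ground_truth = file.path(dir, "ground_truth.json"))
  write_temperature_csv(lapply(bundle$animals, `[[`, "temperature"), paths["temperature"])
  write_hormone_csv(lapply(bundle$animals, `[[`, "hormone"), paths["hormone"])
  design <- do.call(rbind, lapply(names(bundle$animals), function(id)
    data.frame(animal_id = id, group = bundle$animals[[id]]$truth$group)))
  utils::write.csv(design, paths["design"], row.names = FALSE, quote = FALSE)
  truths <- lapply(bundle$animals, `[[`, "truth")
  jsonlite::write_json(truths, paths["ground_truth"], auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(paths)
}

#' Pipeline configuration
#'
#' Aggregates every analysis parameter with its standard default: the +/-4 SD
#' despiking rule with 10-minute gap interpolation, Morse `beta = 5`,
#' `gamma = 3` over 1-39 h periods, circadian band 23-25 h, ultradian band
#' 1-3 h, 24 h power smoothing, 2-SD rise and crossing criteria, 4-day cycle
#' blocks, analysis window p26-p74 with phase boundaries at p42 and p59, and
#' the p50-p58 contraceptive window splitting the multi-day FFT spans.
#'
#' @param temperature_csv,hormone_csv,design_csv input file paths, or `NULL`
#'   to simulate a synthetic cohort instead.
#' @param synthetic list with `groups` (labels), `n_per_group` and
#'   `record_window` for the synthetic cohort (used when no input files are
#'   given).
#' @param sim_params a [simulation_params()] for the synthetic cohort.
#' @param preprocess a [preprocess_params()].
#' @param wavelet a [wavelet_params()].
#' @param circadian_band,ultradian_band period bands, hours.
#' @param smooth_window_h power smoothing window, hours.
#' @param analysis_window `c(from, to)` postnatal days (half open).
#' @param block_len estrous cycle block length, days.
#' @param baseline_window fE2 baseline window (days, inclusive).
#' @param rise_sd_multiple,crossing_sd_multiple 2-SD criteria multiples.
#' @param crossing_reference_len days at the start of the analysis window used
#'   as the crossing-time baseline.
#' @param fallback_anchor_day anchor day for day-of-cycle labels in animals
#'   without a detected fE2 rise.
#' @param contraceptive_window `c(start, end)` days of contraceptive dosing;
#'   also splits the FFT spans (rise to start, start to end of record).
#' @param alpha significance level.
#' @param seed integer seed for the synthetic cohort.
#' @param output_dir directory for result files, or `NULL` to skip writing.
#' @return A `run_config` list.
#' @export
run_config <- function(temperature_csv = NULL, hormone_csv = NULL,
                       design_csv = NULL,
                       synthetic = list(groups = c("Intact", "IntactC", "OVX", "OVX_E2"),
                                        n_per_group = 8,
                                        record_window = c(25, 75)),
                       sim_params = simulation_params(),
                       preprocess = preprocess_params(),
                       wavelet = wavelet_params(),
                       circadian_band = c(23, 25),
                       ultradian_band = c(1, 3),
                       smooth_window_h = 24,
                       analysis_window = c(26, 75),
                       block_len = 4,
                       baseline_window = c(25, 30),
                       rise_sd_multiple = 2,
                       crossing_sd_multiple = 2,
                       crossing_reference_len = 3,
                       fallback_anchor_day = 33,
                       contraceptive_window = c(50, 58),
                       alpha = 0.05,
                       seed = 1,
                       output_dir = NULL) {
  cfg <- as.list(environment())
  cfg$phases <- phase_boundaries()
  structure(cfg, class = "run_config")
}

#' Serialize a run configuration to JSON
#'
#' @param config a [run_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else unclass(x)
  plain <- strip(config)
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Restore a run configuration from JSON
#'
#' @param path JSON path written by [write_run_config()].
#' @return A `run_config` equal to the one serialized.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- run_config()
  for (nm in names(raw)) {
    val <- raw[[nm]]
    if (nm %in% c("sim_params", "preprocess", "wavelet", "synthetic", "phases") &&
        is.list(val)) {
      cfg[[nm]][names(val)] <- val
    } else {
      cfg[[nm]] <- val
    }
  }
  cfg
}
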
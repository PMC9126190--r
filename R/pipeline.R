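# per-animal analysis: clean -> wavelet -> band power -> daily summaries ->
# rise detection -> alignment -> combined metric -> crossing & FFT metrics
analyze_animal <- function(ts, hs, group, config) {
  id <- ts$animal_id[1]
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed for animal %s: %s", name, id,
                   conditionMessage(e)), call. = FALSE))
  }
  cleaned <- stage("preprocess", clean_series(ts, config$preprocess))
  aw <- config$analysis_window
  spec <- stage("wavelet", morse_transform(cleaned$series, config$wavelet))
  cr <- stage("band_power", band_max_power(spec, config$circadian_band))
  ur <- stage("band_power", band_max_power(spec, config$ultradian_band))
  cr_s <- stage("smooth", smooth_power(cr, config$smooth_window_h))

  in_window <- function(df) df[df$day >= aw[1] & df$day < aw[2], , drop = FALSE]
  cr_daily <- in_window(stage("daily", daily_band_stat(cr_s)))
  ur_daily <- in_window(stage("daily", daily_band_stat(ur)))
  day <- floor(age_days(cleaned$series))
  cbt_daily <- in_window(data.frame(
    day = sort(unique(day)),
    value = as.numeric(tapply(cleaned$series$temp_c, day, mean, na.rm = TRUE))))

  rise <- tryCatch(detect_rise(hs, config$baseline_window, config$rise_sd_multiple),
                   error = function(e) NULL)
  rise_day <- if (!is.null(rise)) rise$rise_day else NA_integer_
  anchored_on_rise <- !is.na(rise_day)
  align <- stage("align", align_cycles(
    hs, if (anchored_on_rise) rise else config$fallback_anchor_day,
    config$block_len))

  daily <- data.frame(day = cbt_daily$day, cbt_mean = cbt_daily$value,
                      ur_power = ur_daily$value[match(cbt_daily$day, ur_daily$day)])
  comb <- stage("combined_metric", combined_metric(daily))

  crossing <- stage("crossing", crossing_time(
    cr_daily, reference = c(aw[1], aw[1] + config$crossing_reference_len),
    sd_multiple = config$crossing_sd_multiple))

  fft_from <- if (anchored_on_rise) rise_day else config$fallback_anchor_day
  split_day <- config$contraceptive_window[1]
  auc_pre <- tryCatch(fft_band_auc(
    cbt_daily$value[cbt_daily$day >= fft_from & cbt_daily$day < split_day]),
    error = function(e) NA_real_)
  auc_post <- tryCatch(fft_band_auc(
    cbt_daily$value[cbt_daily$day >= split_day]),
    error = function(e) NA_real_)

  fe2_auc <- tryCatch(fe2_cycle_auc(hs, align), error = function(e) NULL)

  list(animal_id = id, group = group, report = cleaned$report,
       cr_daily = cr_daily, ur_daily = ur_daily, cbt_daily = cbt_daily,
       rise = rise, rise_day = rise_day, anchored_on_rise = anchored_on_rise,
       align = align, combined = comb, crossing = crossing,
       fft_auc_pre = auc_pre, fft_auc_post = auc_post, fe2_auc = fe2_auc,
       hormone = hs)
}

# group-mean daily series across animals in one group
group_mean_daily <- function(animals, field) {
  dfs <- lapply(animals, `[[`, field)
  days <- sort(unique(unlist(lapply(dfs, `[[`, "day"))))
  vals <- sapply(dfs, function(d) d$value[match(days, d$day)])
  data.frame(day = days, value = rowMeans(as.matrix(vals), na.rm = TRUE))
}

#' Run the full multiscale rhythm analysis
#'
#' Strings every stage together: input acquisition (CSV files or a simulated
#' cohort), cleaning, Morse wavelet band power, daily summaries, fE2 rise
#' detection and 4-day cycle alignment, the combined ovulatory metric, and the
#' group-level statistics (Mann-Kendall trends in circadian power and CBT per
#' adolescent phase, day-of-cycle Friedman/Dunn tests per group, 2-SD
#' crossing-time comparison, 4-5 day FFT area contrast, per-cycle fE2 AUC
#' comparison, and the mixed-effects regression of circadian power on fE2).
#' Fully deterministic given `config$seed`.
#'
#' @param config a [run_config()].
#' @return A list of class `run_report` with `per_animal` results,
#'   `group_stats`, the `config`, and (when `config$output_dir` is set) a
#'   `manifest` of written files.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  # --- inputs ---------------------------------------------------------------
  if (!is.null(config$temperature_csv)) {
    temps <- read_temperature_csv(config$temperature_csv)
    horms <- read_hormone_csv(config$hormone_csv)
    design <- utils::read.csv(config$design_csv, stringsAsFactors = FALSE)
    groups <- stats::setNames(design$group, design$animal_id)
    ids <- names(temps)
  } else {
    designs <- lapply(config$synthetic$groups, function(g)
      group_design(g, n_animals = config$synthetic$n_per_group,
                   record_window = config$synthetic$record_window))
    bundle <- simulate_cohort(designs, config$sim_params, seed = config$seed)
    temps <- lapply(bundle$animals, `[[`, "temperature")
    horms <- lapply(bundle$animals, `[[`, "hormone")
    groups <- vapply(bundle$animals, function(a) a$truth$group, "")
    ids <- names(bundle$animals)
  }

  per_animal <- lapply(ids, function(id)
    analyze_animal(temps[[id]], horms[[id]], unname(groups[id]), config))
  names(per_animal) <- ids
  by_group <- split(per_animal, vapply(per_animal, `[[`, "", "group"))

  # --- group statistics -------------------------------------------------------
  stats_out <- list()

  trend_rows <- list()
  for (g in names(by_group)) {
    cr_mean <- group_mean_daily(by_group[[g]], "cr_daily")
    cbt_mean <- group_mean_daily(by_group[[g]], "cbt_daily")
    for (ph in names(config$phases)) {
      w <- config$phases[[ph]]
      for (metric in c("cr_power", "cbt")) {
        src <- if (metric == "cr_power") cr_mean else cbt_mean
        v <- src$value[src$day >= w[1] & src$day < w[2]]
        if (length(v) >= 4) {
          mk <- mann_kendall(v)
          trend_rows[[length(trend_rows) + 1]] <-
            data.frame(group = g, phase = ph, metric = metric, S = mk$S,
                       tau = mk$tau, p = mk$p_value)
        }
      }
    }
  }
  stats_out$trends <- do.call(rbind, trend_rows)

  stats_out$day_of_cycle <- lapply(by_group, function(animals) {
    m <- do.call(rbind, lapply(animals, function(a)
      day_of_cycle_matrix(data.frame(day = a$combined$day, value = a$combined$combined),
                          a$align)))
    if (is.null(m) || nrow(m) < 2) return(NULL)
    day_of_cycle_test(m, alpha = config$alpha)
  })

  crossings <- data.frame(
    animal_id = names(per_animal),
    group = vapply(per_animal, `[[`, "", "group"),
    crossing_day = vapply(per_animal, function(a) as.numeric(a$crossing), 0.0),
    row.names = NULL)
  stats_out$crossing_days <- crossings
  cg <- split(crossings$crossing_day, crossings$group)
  cg <- lapply(cg, function(v) v[!is.na(v)])
  cg <- cg[lengths(cg) >= 3]
  stats_out$crossing_test <- if (length(cg) >= 3)
    omnibus_with_dunn(cg, design = "independent", alpha = config$alpha) else NULL

  aucs <- data.frame(
    animal_id = names(per_animal),
    group = vapply(per_animal, `[[`, "", "group"),
    auc_pre = vapply(per_animal, `[[`, 0.0, "fft_auc_pre"),
    auc_post = vapply(per_animal, `[[`, 0.0, "fft_auc_post"),
    row.names = NULL)
  stats_out$fft_auc <- aucs
  if (all(c("Intact", "IntactC") %in% aucs$group)) {
    a <- aucs$auc_post[aucs$group == "Intact"]
    b <- aucs$auc_post[aucs$group == "IntactC"]
    if (sum(!is.na(a)) >= 3 && sum(!is.na(b)) >= 3) {
      stats_out$fft_auc_contrast <- rank_test_two(a, b)
    }
  }

  fe2_groups <- lapply(by_group, function(animals)
    unlist(lapply(animals, function(a) a$fe2_auc$auc)))
  fe2_groups <- fe2_groups[lengths(fe2_groups) >= 3]
  stats_out$fe2_auc_test <- if (length(fe2_groups) >= 3)
    omnibus_with_dunn(fe2_groups, design = "independent", alpha = config$alpha) else NULL

  stats_out$mixed_models <- lapply(by_group, function(animals) {
    d <- do.call(rbind, lapply(animals, function(a) {
      cr <- a$cr_daily
      z <- (cr$value - mean(cr$value)) / stats::sd(cr$value)
      fe2 <- a$hormone$fe2[match(cr$day, a$hormone$day)]
      data.frame(power = z, fe2 = fe2, id = a$animal_id)
    }))
    tryCatch(mixed_cr_fe2(d), error = function(e) NULL)
  })

  report <- structure(list(per_animal = per_animal, group_stats = stats_out,
                           config = config, manifest = NULL),
                      class = "run_report")

  # --- outputs ----------------------------------------------------------------
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    daily <- do.call(rbind, lapply(per_animal, function(a) {
      data.frame(animal_id = a$animal_id, group = a$group, day = a$cbt_daily$day,
                 cbt_mean = a$cbt_daily$value,
                 cr_power_median = a$cr_daily$value[match(a$cbt_daily$day, a$cr_daily$day)],
                 ur_power_median = a$ur_daily$value[match(a$cbt_daily$day, a$ur_daily$day)],
                 fe2 = a$hormone$fe2[match(a$cbt_daily$day, a$hormone$day)])
    }))
    f_daily <- file.path(config$output_dir, "daily_summaries.csv")
    utils::write.csv(daily, f_daily, row.names = FALSE, na = "")

    aligns <- do.call(rbind, lapply(per_animal, function(a)
      cbind(animal_id = a$animal_id, group = a$group, a$align$labels)))
    f_align <- file.path(config$output_dir, "cycle_alignment.csv")
    utils::write.csv(aligns, f_align, row.names = FALSE)

    summary_rows <- data.frame(
      animal_id = names(per_animal),
      group = vapply(per_animal, `[[`, "", "group"),
      rise_day = vapply(per_animal, function(a) as.numeric(a$rise_day), 0.0),
      crossing_day = crossings$crossing_day,
      fft_auc_pre = aucs$auc_pre, fft_auc_post = aucs$auc_post,
      outliers_replaced = vapply(per_animal, function(a) a$report$outliers_replaced, 0L),
      row.names = NULL)
    f_sum <- file.path(config$output_dir, "animal_summary.csv")
    utils::write.csv(summary_rows, f_sum, row.names = FALSE, na = "")

    f_stats <- file.path(config$output_dir, "group_stats.json")
    jsonlite::write_json(serialize_stats(stats_out), f_stats,
                         auto_unbox = TRUE, digits = 10, null = "null", na = "null")

    files <- c(f_daily, f_align, f_sum, f_stats)
    manifest <- list(seed = config$seed,
                     files = data.frame(file = basename(files),
                                        md5 = unname(tools::md5sum(files))))
    f_manifest <- file.path(config$output_dir, "manifest.json")
    jsonlite::write_json(manifest, f_manifest, auto_unbox = TRUE, digits = NA)
    report$manifest <- manifest
  }
  report
}

# plain-list view of the statistics block for JSON output
serialize_stats <- function(stats_out) {
  strip <- function(x) {
    if (inherits(x, "comparison_result")) {
      return(list(test = x$test, statistic = x$statistic, p_value = x$p_value,
                  pairwise = if (!is.null(x$pairwise)) unclass(as.data.frame(x$pairwise))))
    }
    if (inherits(x, "mixed_model_result")) {
      return(list(slope = x$slope, intercept = x$intercept,
                  r2_marginal = x$r2_marginal, AIC = x$AIC, fallback = x$fallback))
    }
    if (is.list(x) && !is.data.frame(x)) return(lapply(x, strip))
    x
  }
  strip(stats_out)
}

#' @export
print.run_report <- function(x, ...) {
  groups <- table(vapply(x$per_animal, `[[`, "", "group"))
  cat("<run_report>\n")
  cat("  animals:", paste(sprintf("%s (n=%d)", names(groups), groups), collapse = ", "), "\n")
  tr <- x$group_stats$trends
  if (!is.null(tr)) {
    up <- tr[tr$metric == "cr_power" & tr$phase == "pre_mid", ]
    cat("  circadian power trend p26-p41 (group-mean Mann-Kendall):\n")
    for (i in seq_len(nrow(up)))
      cat(sprintf("    %-8s S = %4d, p = %.3g\n", up$group[i], up$S[i], up$p[i]))
  }
  for (g in names(x$group_stats$day_of_cycle)) {
    r <- x$group_stats$day_of_cycle[[g]]
    if (!is.null(r))
      cat(sprintf("  day-of-cycle Friedman %-8s chi2 = %6.1f, p = %.3g\n",
                  g, r$statistic, r$p_value))
  }
  if (!is.null(x$group_stats$fft_auc_contrast)) {
    r <- x$group_stats$fft_auc_contrast
    cat(sprintf("  4-5 day FFT AUC Intact vs IntactC: U = %g, p = %.3g\n",
                r$statistic, r$p_value))
  }
  invisible(x)
}
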
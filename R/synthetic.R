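#' Cohort group design
#'
#' Describes one experimental group of the four-arm adolescent design: `Intact`
#' (sham-operated, freely cycling), `IntactC` (intact with a daily combined
#' contraceptive regimen over `contraceptive_window`), `OVX` (ovariectomized at
#' weaning) and `OVX_E2` (ovariectomized with a tonic estradiol capsule from
#' `capsule_day`).
#'
#' @param group_label one of `"Intact"`, `"IntactC"`, `"OVX"`, `"OVX_E2"`.
#' @param n_animals animals in the group (default 8).
#' @param ovx_day postnatal day of ovariectomy (OVX groups only; default 21).
#' @param capsule_day postnatal day of capsule implant (OVX groups; default 29).
#' @param contraceptive_window `c(start, end)` postnatal days of daily
#'   contraceptive dosing (IntactC only; default `c(50, 58)`).
#' @param record_window `c(start, end)` postnatal days covered by the CBT
#'   record (default `c(25, 75)`; the end day is exclusive for the minute grid).
#' @return A `group_design` list.
#' @export
group_design <- function(group_label = c("Intact", "IntactC", "OVX", "OVX_E2"),
                         n_animals = 8,
                         ovx_day = if (group_label %in% c("OVX", "OVX_E2")) 21 else NA,
                         capsule_day = if (group_label %in% c("OVX", "OVX_E2")) 29 else NA,
                         contraceptive_window = if (group_label == "IntactC") c(50, 58) else NULL,
                         record_window = c(25, 75)) {
  group_label <- match.arg(group_label)
  stopifnot(n_animals >= 1, length(record_window) == 2,
            record_window[1] < record_window[2])
  if (!is.null(contraceptive_window) && group_label != "IntactC") {
    stop("contraceptive_window is only meaningful for the IntactC group")
  }
  if (!is.na(capsule_day) && !group_label %in% c("OVX", "OVX_E2")) {
    stop("capsule_day is only meaningful for OVX / OVX_E2 groups")
  }
  structure(list(group_label = group_label, n_animals = as.integer(n_animals),
                 ovx_day = ovx_day, capsule_day = capsule_day,
                 contraceptive_window = contraceptive_window,
                 record_window = record_window),
            class = "group_design")
}

#' Simulation parameters for the synthetic cohort generator
#'
#' Generative counterparts of every analyzed quantity. Defaults encode the
#' study conditions the analysis assumes: a 12:12 light-dark cycle (lights on
#' at 01:00, off at 13:00), a circadian temperature rhythm whose amplitude
#' ramps up across early-to-mid adolescence (p26-p41) then plateaus, a 1-3 h
#' ultradian rhythm of constant mean amplitude, and -- in cycling animals -- a
#' 4-day estrous cycle that begins at an individually drawn onset day between
#' p31 and p36: fecal estradiol rises for three days and falls on the fourth
#' (peak on cycle day 3), while mean temperature is elevated and ultradian
#' amplitude suppressed on the day after the fE2 rise begins (cycle day 2).
#'
#' @param baseline_cbt pre-pubertal mean CBT, degrees C.
#' @param pubertal_cbt_slope linear CBT rise, degrees C per day, applied over
#'   `cbt_ramp_window`.
#' @param cbt_ramp_window `c(start, end)` days of the pubertal CBT rise.
#' @param circadian_period circadian period, hours.
#' @param circadian_amp_initial,circadian_amp_plateau circadian half-amplitude
#'   (degrees C) before and after the ramp.
#' @param circadian_ramp_window `c(start, end)` days of the circadian amplitude
#'   ramp for Intact/IntactC/OVX animals.
#' @param ultradian_period ultradian period, hours (must lie in \[1, 3\]).
#' @param ultradian_amp ultradian half-amplitude, degrees C.
#' @param estrous_cycle_len estrous cycle length in days (4, rarely 5).
#' @param estrous_cbt_effect mean-CBT elevation (degrees C) on cycle day 2.
#' @param estrous_ur_suppression fractional reduction of ultradian amplitude on
#'   cycle day 2, in \[0, 1\].
#' @param fe2_baseline,fe2_baseline_sd pre-pubertal fE2 level and day-to-day
#'   assay scatter, pg/ml. Scatter is drawn from a normal truncated at +/- 2 SD
#'   (assay noise is bounded; a non-cycling animal never crosses the 2-SD rise
#'   criterion by noise alone).
#' @param fe2_cycle_profile 4 additive fE2 increments (pg/ml) over the cycle,
#'   rising for three days with a fall on the fourth; the maximum must sit at
#'   position 3.
#' @param fe2_tonic_e2 tonic fE2 elevation (pg/ml) from the capsule day in
#'   OVX_E2 animals.
#' @param onset_day_range `c(lo, hi)` postnatal days from which each cycling
#'   animal's estrous onset day is drawn uniformly.
#' @param noise_sd stationary SD (degrees C) of the AR(1) physiological noise;
#'   an additional white measurement noise with SD `noise_sd / 2` is added.
#' @param ar1_coef lag-1 autocorrelation of the physiological noise, in \[0, 1).
#' @param lights_on_hour,lights_off_hour clock hours of the light transitions;
#'   the circadian peak is placed at mid-scotophase.
#' @param ovx_cr_plateau_frac fraction of `circadian_amp_plateau` reached by
#'   OVX animals (depressed circadian power).
#' @param ovx_cbt_decline_slope late CBT decline in OVX animals, degrees C per
#'   day from `ovx_decline_day` on.
#' @param ovx_decline_day postnatal day the OVX decline begins.
#' @param ovxe2_ramp_window steeper circadian ramp window for OVX_E2 animals
#'   (estradiol accelerates the circadian power rise).
#' @param contra_cbt_drop,contra_cr_amp_drop persistent offsets (degrees C)
#'   subtracted from mean CBT and circadian amplitude from the first
#'   contraceptive day on; estrous modulation of fE2/CBT/UR is simultaneously
#'   abolished. These effect sizes are free parameters of the simulator, not
#'   estimates.
#' @return A `simulation_params` list.
#' @export
simulation_params <- function(baseline_cbt = 36.8,
                              pubertal_cbt_slope = 0.025,
                              cbt_ramp_window = c(26, 41),
                              circadian_period = 24,
                              circadian_amp_initial = 0.15,
                              circadian_amp_plateau = 0.45,
                              circadian_ramp_window = c(26, 41),
                              ultradian_period = 2,
                              ultradian_amp = 0.25,
                              estrous_cycle_len = 4,
                              estrous_cbt_effect = 0.25,
                              estrous_ur_suppression = 0.5,
                              fe2_baseline = 20,
                              fe2_baseline_sd = 2,
                              fe2_cycle_profile = c(15, 30, 45, 5),
                              fe2_tonic_e2 = 15,
                              onset_day_range = c(31, 36),
                              noise_sd = 0.15,
                              ar1_coef = 0.9,
                              lights_on_hour = 1,
                              lights_off_hour = 13,
                              ovx_cr_plateau_frac = 0.45,
                              ovx_cbt_decline_slope = 0.02,
                              ovx_decline_day = 58,
                              ovxe2_ramp_window = c(26, 34),
                              contra_cbt_drop = 0.2,
                              contra_cr_amp_drop = 0.1) {
  p <- as.list(environment())
  amps <- c(p$circadian_amp_initial, p$circadian_amp_plateau, p$ultradian_amp,
            p$estrous_cbt_effect, p$noise_sd, p$fe2_baseline_sd)
  if (any(amps < 0)) stop("amplitudes and noise SDs must be non-negative")
  if (!p$estrous_cycle_len %in% c(4, 5)) stop("estrous_cycle_len must be 4 or 5")
  if (length(p$fe2_cycle_profile) != p$estrous_cycle_len ||
      (any(p$fe2_cycle_profile != 0) && which.max(p$fe2_cycle_profile) != 3)) {
    stop("fe2_cycle_profile must have estrous_cycle_len levels with its maximum at position 3 (or be all zero for a null cycle)")
  }
  if (p$ultradian_period < 1 || p$ultradian_period > 3) {
    stop("ultradian_period must lie in [1, 3] hours")
  }
  if (p$ar1_coef < 0 || p$ar1_coef >= 1) stop("ar1_coef must lie in [0, 1)")
  if (p$estrous_ur_suppression < 0 || p$estrous_ur_suppression > 1) {
    stop("estrous_ur_suppression must lie in [0, 1]")
  }
  structure(p, class = "simulation_params")
}

# normal deviates truncated at +/- 2 SD (inverse-CDF method, deterministic
# given the RNG state)
rtrunc2 <- function(n, sd) {
  if (sd == 0 || n == 0) return(rep(0, n))
  lo <- stats::pnorm(-2); hi <- stats::pnorm(2)
  stats::qnorm(stats::runif(n, lo, hi)) * sd
}

# piecewise-linear ramp: value v0 before w[1], v1 after w[2]
ramp_value <- function(day, w, v0, v1) {
  frac <- pmin(pmax((day - w[1]) / (w[2] - w[1]), 0), 1)
  v0 + frac * (v1 - v0)
}

#' Simulate one animal's temperature and hormone record
#'
#' Generates a minute-binned CBT series and a daily fE2 series following the
#' group template in `design`, together with the ground truth used by
#' parameter-recovery tests. Cycling groups (Intact, IntactC) draw an estrous
#' onset day uniformly from `params$onset_day_range`; from that day fE2 follows
#' repeating `fe2_cycle_profile` blocks (peak on cycle day 3), mean CBT is
#' elevated by `estrous_cbt_effect` and ultradian amplitude suppressed by
#' `estrous_ur_suppression` on cycle day 2. IntactC animals lose all estrous
#' modulation permanently from the first contraceptive day and acquire fixed
#' negative offsets on CBT and circadian amplitude. OVX animals never cycle,
#' reach a depressed circadian plateau and decline in CBT from
#' `ovx_decline_day`; OVX_E2 animals never cycle but ramp circadian amplitude
#' faster and maintain CBT.
#'
#' @param design a [group_design()].
#' @param params a [simulation_params()].
#' @param seed integer RNG seed; identical `(design, params, seed)` reproduce
#'   the output exactly.
#' @param animal_id identifier for the generated animal.
#' @return A list of class `animal_record` with elements `temperature`
#'   ([temperature_series()]), `hormone` ([hormone_series()]) and `truth`, a
#'   list holding the drawn `onset_day` (NA for non-cycling groups), per-day
#'   `cycle_phase` (1-4, NA before onset / after abolition), per-day circadian
#'   amplitude, CBT level and ultradian amplitude, and the component settings.
#' @export
simulate_animal <- function(design, params = simulation_params(), seed = 1,
                            animal_id = design$group_label) {
  stopifnot(inherits(design, "group_design"), inherits(params, "simulation_params"))
  rw <- design$record_window
  if (diff(rw) < 10) stop("record_window must span at least 10 days")
  set.seed(as.integer(seed))

  days <- seq.int(rw[1], rw[2] - 1L)        # one fE2 value per covered day
  n_days <- length(days)
  age_min <- seq.int(rw[1] * 1440, rw[2] * 1440 - 1L)
  t_day <- age_min / 1440

  cycling <- design$group_label %in% c("Intact", "IntactC")
  onset <- NA_integer_
  if (cycling) {
    onset <- as.integer(round(stats::runif(1, params$onset_day_range[1],
                                           params$onset_day_range[2])))
  }
  contra_start <- if (design$group_label == "IntactC")
    design$contraceptive_window[1] else Inf

  clen <- params$estrous_cycle_len
  # per-day cycle phase; estrous modulation active while cycling and (for
  # IntactC) before contraceptive onset
  phase <- rep(NA_integer_, n_days)
  if (cycling) {
    idx <- days >= onset & days < contra_start
    phase[idx] <- ((days[idx] - onset) %% clen) + 1L
  }

  ## --- daily fE2 -----------------------------------------------------------
  fe2 <- rep(params$fe2_baseline, n_days) + rtrunc2(n_days, params$fe2_baseline_sd)
  if (cycling) fe2[!is.na(phase)] <- fe2[!is.na(phase)] +
    params$fe2_cycle_profile[phase[!is.na(phase)]]
  if (design$group_label == "OVX_E2") {
    fe2[days >= design$capsule_day] <- fe2[days >= design$capsule_day] +
      params$fe2_tonic_e2
  }
  fe2 <- pmax(fe2, 0)

  ## --- per-day component amplitudes ---------------------------------------
  cr_w <- if (design$group_label == "OVX_E2") params$ovxe2_ramp_window else
    params$circadian_ramp_window
  cr_hi <- if (design$group_label == "OVX")
    params$circadian_amp_plateau * params$ovx_cr_plateau_frac else
    params$circadian_amp_plateau
  amp_cr_day <- ramp_value(days, cr_w, params$circadian_amp_initial, cr_hi)
  amp_cr_day[days >= contra_start] <-
    pmax(amp_cr_day[days >= contra_start] - params$contra_cr_amp_drop, 0)

  level_day <- params$baseline_cbt + params$pubertal_cbt_slope *
    (pmin(pmax(days, params$cbt_ramp_window[1]), params$cbt_ramp_window[2]) -
       params$cbt_ramp_window[1])
  if (design$group_label == "OVX") {
    late <- days >= params$ovx_decline_day
    level_day[late] <- level_day[late] -
      params$ovx_cbt_decline_slope * (days[late] - params$ovx_decline_day)
  }
  level_day[days >= contra_start] <-
    level_day[days >= contra_start] - params$contra_cbt_drop
  est_day <- !is.na(phase) & phase == 2L
  level_day[est_day] <- level_day[est_day] + params$estrous_cbt_effect

  amp_ur_day <- rep(params$ultradian_amp, n_days)
  amp_ur_day[est_day] <- amp_ur_day[est_day] * (1 - params$estrous_ur_suppression)

  ## --- minute-resolution signal -------------------------------------------
  di <- findInterval(t_day, days)           # day index per minute
  clock_h <- (age_min / 60) %% 24
  peak_h <- ((params$lights_on_hour + 24 + params$lights_off_hour) / 2) %% 24
  circ <- amp_cr_day[di] *
    cos(2 * pi * (clock_h - peak_h) / params$circadian_period)
  ultra <- amp_ur_day[di] *
    cos(2 * pi * age_min / (params$ultradian_period * 60))

  noise <- numeric(length(age_min))
  if (params$noise_sd > 0) {
    innov_sd <- params$noise_sd * sqrt(1 - params$ar1_coef^2)
    ar <- as.numeric(stats::filter(stats::rnorm(length(age_min), 0, innov_sd),
                                   params$ar1_coef, method = "recursive"))
    noise <- ar + stats::rnorm(length(age_min), 0, params$noise_sd / 2)
  }

  temp <- level_day[di] + circ + ultra + noise

  truth <- list(group = design$group_label, onset_day = onset,
                days = days, cycle_phase = phase,
                circadian_amp = amp_cr_day, cbt_level = level_day,
                ultradian_amp = amp_ur_day,
                circadian_ramp_window = cr_w,
                contra_start = if (is.finite(contra_start)) contra_start else NA,
                seed = as.integer(seed))

  structure(list(temperature = temperature_series(animal_id, age_min, temp),
                 hormone = hormone_series(animal_id, days, fe2),
                 truth = truth),
            class = "animal_record")
}

#' Simulate a multi-group cohort
#'
#' Draws every animal of every design with per-animal seeds derived
#' deterministically from `seed`, so the whole bundle is reproducible.
#'
#' @param designs a list of [group_design()] objects (distinct group labels).
#' @param params a [simulation_params()].
#' @param seed master integer seed.
#' @return A list of class `cohort_bundle` with elements `animals` (named list
#'   of `animal_record`s, ids `<group>_<i>`), `designs`, `params`, `seed`.
#' @export
simulate_cohort <- function(designs, params = simulation_params(), seed = 1) {
  if (inherits(designs, "group_design")) designs <- list(designs)
  if (length(designs) < 1) stop("need at least one group design")
  labels <- vapply(designs, `[[`, "", "group_label")
  ids <- unlist(lapply(designs, function(d)
    paste0(d$group_label, "_", seq_len(d$n_animals))))
  if (anyDuplicated(ids)) stop("duplicate animal ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  set.seed(as.integer(seed))
  animal_seeds <- sample.int(.Machine$integer.max - 1L, length(ids))
  animals <- vector("list", length(ids))
  k <- 0L
  for (d in designs) {
    for (i in seq_len(d$n_animals)) {
      k <- k + 1L
      animals[[k]] <- simulate_animal(d, params, seed = animal_seeds[k],
                                      animal_id = ids[k])
    }
  }
  names(animals) <- ids
  structure(list(animals = animals, designs = designs, params = params,
                 seed = as.integer(seed)),
            class = "cohort_bundle")
}

#' Artifact specification for stress-testing the preprocessor
#'
#' @param spike_rate spike events per day (deterministic count:
#'   `round(spike_rate * n_days)`).
#' @param spike_magnitude_sd spike size as a multiple of the series SD; must
#'   exceed 4 so the +/-4 SD despiking rule can see it.
#' @param gap_rate short-gap events per day (deterministic count as above).
#' @param gap_length_min length of each short gap, minutes (default < 10 so the
#'   gap-interpolation rule applies).
#' @param long_gap_count number of long (> 10 min) gaps over the whole record,
#'   for negative tests; each is `long_gap_length_min` long.
#' @param long_gap_length_min length of each long gap, minutes.
#' @return An `artifact_spec` list.
#' @export
artifact_spec <- function(spike_rate = 0, spike_magnitude_sd = 6,
                          gap_rate = 0, gap_length_min = 5,
                          long_gap_count = 0, long_gap_length_min = 30) {
  stopifnot(spike_rate >= 0, gap_rate >= 0, long_gap_count >= 0)
  if (spike_magnitude_sd <= 4) {
    stop("spike_magnitude_sd must exceed 4 (smaller spikes are invisible to the +/-4 SD rule by construction)")
  }
  structure(list(spike_rate = spike_rate, spike_magnitude_sd = spike_magnitude_sd,
                 gap_rate = gap_rate, gap_length_min = gap_length_min,
                 long_gap_count = long_gap_count,
                 long_gap_length_min = long_gap_length_min),
            class = "artifact_spec")
}

#' Inject spikes and gaps into a temperature series
#'
#' Returns a copy of `series` with seeded spike artifacts (additive
#' `spike_magnitude_sd` series-SD deviations of random sign) and runs of
#' missing samples. Spike and gap positions are recorded in the
#' `"artifacts"` attribute for positional test assertions.
#'
#' @param series a [temperature_series()].
#' @param spec an [artifact_spec()].
#' @param seed integer RNG seed.
#' @return The corrupted `temperature_series`; `attr(x, "artifacts")` holds
#'   `spike_idx` and `gap_runs` (list of index vectors).
#' @export
inject_artifacts <- function(series, spec, seed = 1) {
  stopifnot(inherits(series, "temperature_series"), inherits(spec, "artifact_spec"))
  n <- nrow(series)
  if (n == 0) stop("empty series")
  set.seed(as.integer(seed))
  n_days <- n / 1440
  n_spikes <- round(spec$spike_rate * n_days)
  gaps_wanted <- c(rep(spec$gap_length_min, round(spec$gap_rate * n_days)),
                   rep(spec$long_gap_length_min, spec$long_gap_count))

  temp <- series$temp_c
  gap_runs <- list()
  taken <- rep(FALSE, n)
  for (len in gaps_wanted) {
    for (try in 1:1000) {
      start <- sample.int(n - len + 1L, 1)
      idx <- start:(start + len - 1L)
      if (!any(taken[idx])) break
    }
    taken[idx] <- TRUE
    gap_runs <- c(gap_runs, list(idx))
  }
  spike_idx <- integer(0)
  if (n_spikes > 0) {
    pool <- which(!taken & !is.na(temp))
    spike_idx <- sort(sample(pool, n_spikes))
    s <- sample(c(-1, 1), n_spikes, replace = TRUE)
    temp[spike_idx] <- temp[spike_idx] +
      s * spec$spike_magnitude_sd * stats::sd(temp, na.rm = TRUE)
  }
  for (idx in gap_runs) temp[idx] <- NA_real_
  out <- series
  out$temp_c <- temp
  attr(out, "artifacts") <- list(spike_idx = spike_idx, gap_runs = gap_runs)
  out
}
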
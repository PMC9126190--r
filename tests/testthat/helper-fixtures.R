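# shared fixture builders (all data generated in code)

# pure tone temperature series: amp * cos(2*pi*t / period_h) around 37 C
tone_series <- function(period_h, days = 20, amp = 1, start_day = 25,
                        id = "tone") {
  n <- days * 1440
  t <- seq_len(n) - 1
  temperature_series(id, t + start_day * 1440,
                     37 + amp * cos(2 * pi * t / (period_h * 60)))
}

# constant temperature series
constant_series <- function(value = 37, days = 2, start_day = 25, id = "const") {
  n <- days * 1440
  temperature_series(id, seq_len(n) - 1 + start_day * 1440, rep(value, n))
}

# time-averaged wavelet power per period over the edge-valid region
avg_power <- function(spec) {
  colMeans(spec$power * ifelse(spec$valid, 1, NA), na.rm = TRUE)
}

# zeroed simulation: no rhythms, no noise, flat hormone
null_params <- function(...) {
  args <- list(pubertal_cbt_slope = 0, circadian_amp_initial = 0,
               circadian_amp_plateau = 0, ultradian_amp = 0,
               estrous_cbt_effect = 0, estrous_ur_suppression = 0,
               fe2_baseline_sd = 0, fe2_cycle_profile = c(0, 0, 0, 0),
               noise_sd = 0, ovx_cr_plateau_frac = 1,
               ovx_cbt_decline_slope = 0, contra_cbt_drop = 0,
               contra_cr_amp_drop = 0, fe2_tonic_e2 = 0)
  over <- list(...)
  args[names(over)] <- over
  do.call(simulation_params, args)
}

# daily mean CBT data frame from a temperature series
daily_cbt <- function(ts) {
  day <- floor(age_days(ts))
  data.frame(day = sort(unique(day)),
             value = as.numeric(tapply(ts$temp_c, day, mean, na.rm = TRUE)))
}

# brute-force Mann-Kendall oracle: direct pairwise enumeration
mk_oracle <- function(x) {
  n <- length(x)
  s <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) s <- s + sign(x[j] - x[i])
  ties <- table(x)
  denom <- sqrt((n * (n - 1) / 2 - sum(ties * (ties - 1)) / 2) * (n * (n - 1) / 2))
  list(S = as.integer(s), tau = if (denom > 0) s / denom else 0)
}
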
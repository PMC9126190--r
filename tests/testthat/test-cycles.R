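test_that("rise detection follows the baseline + 2 SD rule", {
  # constant series: never rises
  flat <- hormone_series("a", 25:50, rep(10, 26))
  det <- detect_rise(flat)
  expect_true(is.na(det$rise_day))
  expect_true(det$threshold_undefined)
  # hand-computed fixture: baseline p25-p30 = {10,11,9,10,10,10},
  # mean 10, sd 0.6325, threshold 11.265; days 31-32 = 11 stay below,
  # day 33 = 14 is the first exceedance
  h <- hormone_series("b", 25:33, c(10, 11, 9, 10, 10, 10, 11, 11, 14))
  det <- detect_rise(h)
  expect_equal(det$baseline_mean, 10)
  expect_equal(det$baseline_sd, sd(c(10, 11, 9, 10, 10, 10)))
  expect_equal(det$rise_day, 33L)
  # unobserved baseline is an error
  expect_error(detect_rise(hormone_series("c", 28:40, rep(1, 13))),
               "not fully observed")
})

test_that("rise detection recovers the generator's onset for Intact cohorts", {
  b <- simulate_cohort(list(group_design("Intact", n_animals = 8)),
                       simulation_params(), seed = 31)
  for (a in b$animals) {
    det <- detect_rise(a$hormone)
    expect_false(is.na(det$rise_day))
    expect_true(det$rise_day >= 31 && det$rise_day <= 36)
    expect_equal(det$rise_day, a$truth$onset_day)
  }
})

test_that("cycle alignment anchors the fE2 peak at day 3", {
  # repeating [1,2,3,0.5] from the rise: peak index 3 in every block
  h <- hormone_series("a", 25:52, c(rep(0.2, 6), rep(c(1, 2, 3, 0.5), 5), 1, 2))
  det <- detect_rise(h)
  expect_equal(det$rise_day, 31L)
  al <- align_cycles(h, det)
  expect_equal(al$anchor_day, 31L)
  expect_equal(al$peak_day_index, 3L)
  m <- day_of_cycle_matrix(data.frame(day = h$day, value = h$fe2), al)
  expect_true(all(apply(m, 1, which.max) == 3))
  # rotating the pattern by one day shifts the anchor so the peak returns to 3
  h2 <- hormone_series("b", 25:52, c(rep(0.2, 6), rep(c(2, 3, 0.5, 1), 5), 2, 3))
  al2 <- align_cycles(h2, detect_rise(h2))
  lab2 <- al2$labels
  peak_days <- h2$day[h2$fe2 == 3]
  expect_true(all(lab2$day_of_cycle[match(peak_days, lab2$day)] == 3))
  # a single complete block still aligns with labels 1..4
  h3 <- hormone_series("c", 25:34, c(rep(0.2, 6), 1, 2, 3, 0.5))
  al3 <- align_cycles(h3, detect_rise(h3))
  expect_equal(sum(al3$labels$complete), 4)
  expect_setequal(al3$labels$day_of_cycle[al3$labels$complete], 1:4)
  expect_error(align_cycles(hormone_series("d", 25:32, c(rep(0.2, 6), 1, 2)),
                            detect_rise(h3)), "rise")
})

test_that("alignment recovery: exact without noise, >= 95% with 25% noise", {
  # noiseless: every labeled day matches the ground-truth phase
  rec <- simulate_animal(group_design("Intact"),
                         simulation_params(fe2_baseline_sd = 0, noise_sd = 0),
                         seed = 17)
  al <- align_cycles(rec$hormone, detect_rise(rec$hormone))
  truth <- rec$truth$cycle_phase[match(al$labels$day, rec$truth$days)]
  expect_equal(al$labels$day_of_cycle, unname(truth))
  # noisy: profile range is 40 pg/ml; sd 10 = 25% of cycle amplitude
  agree <- 0; total <- 0
  for (seed in 1:20) {
    rec <- simulate_animal(group_design("Intact"),
                           simulation_params(fe2_baseline_sd = 10), seed = seed)
    det <- detect_rise(rec$hormone)
    if (is.na(det$rise_day)) next
    al <- align_cycles(rec$hormone, det)
    truth <- rec$truth$cycle_phase[match(al$labels$day, rec$truth$days)]
    ok <- !is.na(truth)
    agree <- agree + sum(al$labels$day_of_cycle[ok] == truth[ok])
    total <- total + sum(ok)
  }
  expect_gte(agree / total, 0.95)
})

test_that("the combined metric matches hand-computed z-scores and is affine-invariant", {
  daily <- data.frame(day = 1:5, cbt_mean = c(37, 37, 38, 37, 37),
                      ur_power = c(2, 2, 1, 2, 2))
  cm <- combined_metric(daily)
  # sd of both inputs is sqrt(0.2); day 3 combines +0.8/sqrt(0.2) - (-0.8/sqrt(0.2))
  expect_equal(cm$combined[3], 1.6 / sqrt(0.2))
  expect_equal(cm$combined[1], -0.4 / sqrt(0.2))
  # identical z-profiles cancel
  same <- data.frame(day = 1:5, cbt_mean = c(1, 2, 3, 2, 1), ur_power = c(1, 2, 3, 2, 1))
  expect_equal(combined_metric(same)$combined, rep(0, 5))
  # affine rescaling of either input leaves the metric unchanged
  resc <- daily
  resc$cbt_mean <- 10 * resc$cbt_mean - 300
  resc$ur_power <- 0.1 * resc$ur_power + 5
  expect_equal(combined_metric(resc)$combined, cm$combined, tolerance = 1e-12)
  expect_error(combined_metric(data.frame(day = 1:5, cbt_mean = rep(1, 5),
                                          ur_power = 1:5)), "zero variance")
})

test_that("day-of-cycle testing flags programmed structure and not constants", {
  h <- hormone_series("a", 25:62, c(rep(0.2, 6), rep(c(1, 2, 3, 0.5), 8)))
  al <- align_cycles(h, detect_rise(h))
  # constant metric: Friedman p ~ 1
  const <- data.frame(day = h$day, value = rep(1, nrow(h)))
  res <- day_of_cycle_test(const, al)
  expect_gt(res$p_value, 0.5)
  # one elevated day, others tied: omnibus p < 0.01 and the elevated day wins
  # every Dunn comparison
  lab <- al$labels
  v <- c(0.1, 0.1, 5, 0.1)[lab$day_of_cycle]
  res2 <- day_of_cycle_test(data.frame(day = lab$day, value = v), al)
  expect_lt(res2$p_value, 0.01)
  expect_true(res2$omnibus_significant)
  expect_true(all(res2$pairwise[3, -3] < 0.05))
})

test_that("5-day re-binning of 4-day structure dilutes day-of-cycle separation", {
  rec <- simulate_animal(group_design("Intact"),
                         simulation_params(fe2_baseline_sd = 0, noise_sd = 0.05),
                         seed = 23)
  det <- detect_rise(rec$hormone)
  ur_amp <- rec$truth$ultradian_amp
  cbt <- rec$truth$cbt_level
  daily <- data.frame(day = rec$truth$days, cbt_mean = cbt + 1e-4 * sin(rec$truth$days),
                      ur_power = ur_amp^2 + 1e-4 * cos(rec$truth$days))
  cm <- combined_metric(daily)
  vals <- data.frame(day = cm$day, value = cm$combined)
  p4 <- day_of_cycle_test(vals, align_cycles(rec$hormone, det, block_len = 4))$p_value
  p5 <- day_of_cycle_test(vals, align_cycles(rec$hormone, det, block_len = 5))$p_value
  expect_lt(p4, 0.01)
  expect_gt(p5, p4)
})

test_that("spectral band area behaves like an integral", {
  set.seed(8)
  # white noise vs the same plus a unit 4-day sinusoid: AUC larger in nearly
  # every draw (destructive interference at the signal bin leaves a
  # few-percent chance of a reversal at this signal-to-noise ratio)
  wins <- 0
  for (rep in 1:100) {
    noise <- rnorm(24)
    with_sig <- noise + sin(2 * pi * (1:24) / 4)
    if (fft_band_auc(with_sig) > fft_band_auc(noise)) wins <- wins + 1
  }
  expect_gte(wins, 95)
  # pure 4-day tone: spectral peak at 4 days
  tone <- sin(2 * pi * (1:40) / 4)
  expect_equal(fft_peak_period(tone, c(3, 6)), 4)
  # non-negative and additive over disjoint period sub-bands
  y <- rnorm(30)
  expect_gte(fft_band_auc(y, c(4, 5)), 0)
  expect_equal(fft_band_auc(y, c(4, 4.5)) + fft_band_auc(y, c(4.5, 5)),
               fft_band_auc(y, c(4, 5)), tolerance = 1e-10)
  expect_error(fft_band_auc(rnorm(10), c(4, 5)), "too short")
})

test_that("per-cycle fE2 AUC is the block trapezoid", {
  h <- hormone_series("a", 25:42, c(rep(0.2, 6), rep(c(1, 2, 3, 0.5), 3)))
  al <- align_cycles(h, detect_rise(h))
  auc <- fe2_cycle_auc(h, al)
  expect_equal(auc$auc, rep(5.75, nrow(auc)))      # (1+2)/2+(2+3)/2+(3+0.5)/2
  # all-zero block integrates to zero; doubling fE2 doubles the AUC
  hz <- hormone_series("z", 1:4, rep(0, 4))
  expect_equal(pracma::trapz(1:4, hz$fe2), 0)
  h2 <- h; h2$fe2 <- 2 * h$fe2
  class(h2) <- class(h)
  expect_equal(fe2_cycle_auc(h2, al)$auc, 2 * auc$auc)
})
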
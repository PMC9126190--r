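test_that("zero input yields identically zero power", {
  ts <- constant_series(0, days = 5)
  sp <- morse_transform(ts, wavelet_params(period_max_h = 30))
  expect_true(all(sp$power == 0))
  expect_true(all(sp$power >= 0))
})

test_that("a 24 h unit tone peaks at the analytic Morse period within one voice", {
  tone <- tone_series(24, days = 20)
  sp <- morse_transform(tone, wavelet_params(period_min_h = 12, period_max_h = 48))
  avg <- avg_power(sp)
  peak_period <- sp$periods_h[which.max(avg)]
  expect_lt(abs(log2(peak_period / 24)), 1 / 16)
  # cross-check the peak location against an FFT of the same record
  x <- tone$temp_c - mean(tone$temp_c)
  n <- length(x)
  mag <- Mod(stats::fft(x))[2:(n %/% 2)]
  fft_period_h <- n / which.max(mag) / 60
  expect_lt(abs(log2(peak_period / fft_period_h)), 1 / 16)
  # bandpass normalization: unit tone draws unit peak power
  expect_equal(max(avg), 1, tolerance = 0.02)
})

test_that("superimposed 2 h and 24 h tones give maxima in both analysis bands", {
  tone <- tone_series(24, days = 20)
  t <- seq_len(nrow(tone)) - 1
  tone$temp_c <- tone$temp_c + 0.5 * cos(2 * pi * t / (2 * 60))
  sp <- morse_transform(tone)
  avg <- avg_power(sp)
  locmax <- which(diff(sign(diff(avg))) == -2) + 1
  pk <- sp$periods_h[locmax]
  expect_true(any(pk >= 1 & pk <= 3))
  expect_true(any(pk >= 23 & pk <= 25))
  expect_length(pk, 2)
})

test_that("doubling the amplitude quadruples the power everywhere", {
  a <- morse_transform(tone_series(24, days = 10, amp = 0.5),
                       wavelet_params(period_min_h = 20, period_max_h = 30))
  b <- morse_transform(tone_series(24, days = 10, amp = 1),
                       wavelet_params(period_min_h = 20, period_max_h = 30))
  nz <- a$power > 1e-12
  expect_equal(b$power[nz] / a$power[nz], rep(4, sum(nz)), tolerance = 1e-8)
})

test_that("power is shift-covariant inside the valid region", {
  # amplitude-modulated circadian tone observed twice, k minutes apart
  k <- 300
  n <- 12 * 1440
  f <- function(t) (1 + 0.5 * cos(2 * pi * t / (7 * 1440))) *
    cos(2 * pi * t / 1440) + 37
  t0 <- seq_len(n) - 1
  sa <- temperature_series("a", t0 + 40000, f(t0))
  sb <- temperature_series("b", t0 + 40000, f(t0 - k))
  wp <- wavelet_params(period_min_h = 20, period_max_h = 30)
  pa <- morse_transform(sa, wp)$power
  pb <- morse_transform(sb, wp)$power
  interior <- (3 * 1440):(n - 3 * 1440)
  expect_equal(pb[interior, ], pa[interior - k, ], tolerance = 0.01)
})

test_that("the analytic peak mapping holds across the Morse parameter plane", {
  tone <- tone_series(24, days = 12)
  for (b in c(3, 8)) for (g in c(2, 5)) {
    sp <- morse_transform(tone, wavelet_params(beta = b, gamma = g,
                                               period_min_h = 12, period_max_h = 48))
    peak <- sp$periods_h[which.max(avg_power(sp))]
    expect_lt(abs(log2(peak / 24)), 1 / 16)
  }
})

test_that("the valid mask excludes record edges at long periods", {
  sp <- morse_transform(tone_series(24, days = 10),
                        wavelet_params(period_min_h = 12, period_max_h = 48))
  long_col <- which.max(sp$periods_h)
  expect_false(sp$valid[1, long_col])
  expect_false(sp$valid[nrow(sp$valid), long_col])
  expect_true(any(sp$valid[, long_col]))
  # cone widens with period: fewer valid samples at longer periods
  expect_lte(sum(sp$valid[, long_col]), sum(sp$valid[, 1]))
})

test_that("band extraction is exact on a constructed spectrum and monotone in the band", {
  sp <- morse_transform(tone_series(24, days = 15), wavelet_params())
  circ <- band_max_power(sp, c(23, 25))
  ultra <- band_max_power(sp, c(1, 3))
  wide <- band_max_power(sp, c(1, 39))
  # tone at 24 h: circadian band carries the power, ultradian none
  expect_gt(mean(circ$values[circ$valid]), 0.5)
  expect_lt(mean(ultra$values[ultra$valid]), 1e-4)
  # widening the band can only increase the band-max
  expect_true(all(wide$values >= circ$values - 1e-12))
  expect_true(all(wide$values >= ultra$values - 1e-12))
  # a pure tone gives a near-constant circadian band series
  v <- circ$values[circ$valid]
  expect_lt(stats::sd(v) / mean(v), 0.10)
  expect_error(band_max_power(sp, c(50, 60)), "no grid periods")
})

test_that("smoothing: constants unchanged, impulse spreads to 1/window, variance shrinks", {
  n <- 5 * 1440
  mk_bp <- function(values) {
    structure(list(times_min = seq_len(n), values = values,
                   valid = rep(TRUE, n), band = c(23, 25),
                   smoothed = FALSE, normalized = FALSE, animal_id = "x"),
              class = "band_power_series")
  }
  const <- smooth_power(mk_bp(rep(2.5, n)), window_h = 24)
  expect_equal(const$values, rep(2.5, n))
  imp <- smooth_power(mk_bp(c(rep(0, 3000), 1, rep(0, n - 3001))), window_h = 24)
  expect_equal(max(imp$values), 1 / 1440)
  expect_equal(sum(imp$values > 0), 1440)
  set.seed(4)
  noisy <- mk_bp(abs(rnorm(n)))
  s1 <- smooth_power(noisy, window_h = 24)
  s2 <- smooth_power(s1, window_h = 24)
  expect_lte(stats::var(s2$values), stats::var(s1$values))
})

test_that("normalization: affine invariance and reference semantics", {
  sp <- morse_transform(tone_series(24, days = 15))
  bp <- band_max_power(sp, c(23, 25))
  bp$values <- bp$values + seq(0, 1, length.out = length(bp$values)) # non-constant
  z1 <- normalize_power(bp)
  aff <- bp; aff$values <- 3.2 * bp$values + 7
  z2 <- normalize_power(aff)
  expect_equal(z1$values, z2$values, tolerance = 1e-10)
  # reference = whole record: mean 0, sd 1 over the valid region
  expect_equal(mean(z1$values[z1$valid]), 0, tolerance = 1e-10)
  expect_equal(stats::sd(z1$values[z1$valid]), 1, tolerance = 1e-10)
  # constant-in-reference series is rejected
  flat <- bp; flat$values <- rep(2, length(bp$values))
  expect_error(normalize_power(flat), "zero SD")
})

test_that("crossing time finds the first day above the 2-SD criterion", {
  below <- data.frame(day = 26:50, value = rep(1, 25) + sin(26:50) * 0.01)
  expect_true(is.na(crossing_time(below, reference = c(26, 31))))
  step <- data.frame(day = 26:50, value = c(rep(1, 7), rep(5, 18)) +
                       0.001 * sin(26:50))
  expect_equal(crossing_time(step, reference = c(26, 31)), 33)
  expect_error(crossing_time(step, reference = c(80, 85)), "outside")
})

test_that("steeper circadian ramps cross the criterion no later, same seed", {
  wp <- wavelet_params(period_min_h = 23, period_max_h = 25)
  xt <- function(group, seed) {
    rec <- simulate_animal(group_design(group), simulation_params(), seed = seed)
    sp <- morse_transform(clean_series(rec$temperature)$series, wp)
    cd <- daily_band_stat(smooth_power(band_max_power(sp, c(23, 25))))
    crossing_time(cd, reference = c(26, 29))
  }
  crossings <- vapply(1:5, function(s) c(xt("Intact", s), xt("OVX_E2", s)), c(0, 0))
  expect_true(all(crossings[2, ] <= crossings[1, ]))
})
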
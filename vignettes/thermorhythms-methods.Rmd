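---
title: "Methods: multiscale rhythm analysis of continuous core body temperature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiscale rhythm analysis of continuous core body temperature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(thermorhythms)
```

## Scope

`thermorhythms` analyzes continuous, minute-binned core body temperature
(CBT) records from adolescent female rodents together with daily fecal
estradiol (fE2) assays. Three rhythm scales are quantified:

* **ultradian (UR)**: oscillations with periods of 1–3 h;
* **circadian (CR)**: the ~24 h rhythm, quantified as 23–25 h wavelet band
  power;
* **ovulatory (OR)**: the rat's ~4-day estrous cycle, which modulates both
  CBT level and ultradian power.

The package also ships a synthetic-cohort simulator whose templates mirror
four experimental conditions: gonadally intact animals (`Intact`), intact
animals given a combined oral contraceptive from p50–p58 (`IntactC`),
ovariectomized animals (`OVX`), and ovariectomized animals with a
constant-release estradiol capsule (`OVX_E2`). Every stage of the analysis
can therefore be validated against known ground truth.

## Preprocessing

Telemetry records contain transmission spikes and dropouts. `clean_series()`
applies, in order:

1. **Despiking.** Samples more than 4 SD from the record mean (both computed
   once, from the raw record) are replaced by the median of the preceding
   60 min of retained values. The prior-hour median is robust to the spike
   itself and to short local trends; replacements proceed left to right so a
   replaced value can serve later windows.
2. **Jump removal.** Implausible minute-to-minute jumps are handled by the
   same replacement rule, iterated until no jump exceeds the cutoff.
3. **Gap interpolation.** Runs of missing samples up to 10 min are linearly
   interpolated (`zoo::na.approx` with `maxgap`); longer gaps are preserved
   as missing so they cannot manufacture rhythm power.

The rules are idempotent: re-cleaning a cleaned record changes nothing,
which is asserted in the test suite. `clean_series()` returns a
`cleaning_report` counting every action taken.

Developmental phases are fixed windows: pre/mid-pubertal p26–p41,
mid–late p42–p58, late–adult p59–p74 (`phase_boundaries()`,
`segment_phases()`; intervals are half-open on the right).

## Generalized Morse wavelet transform

The continuous wavelet transform uses the generalized Morse family, defined
in the frequency domain by

$$\Psi_{\beta,\gamma}(\omega) = a_{\beta,\gamma}\, \omega^{\beta}
  e^{-\omega^{\gamma}}, \qquad \omega > 0,$$

with peak (carrier) frequency $\omega_c = (\beta/\gamma)^{1/\gamma}$. The
defaults $\beta = 5$, $\gamma = 3$ give a nearly symmetric, analytic wavelet
with a good time–frequency compromise for hour-to-day scale physiology.
Implementation choices:

* **Bandpass normalization** $a = 2(e\gamma/\beta)^{\beta/\gamma}$ so that
  $\Psi(\omega_c) = 2$: a unit-amplitude sinusoid returns unit wavelet
  power at its period, making band power directly interpretable in
  (°C)².
* **Analytic transform**: only positive frequencies contribute, so power is
  the squared modulus of a complex coefficient and amplitude modulation is
  demodulated cleanly.
* **FFT evaluation** with zero-padding to a highly composite length at
  least `n + 2 × (longest period in samples)`, preventing wrap-around
  leakage between the record's ends.
* **Log-spaced period grid**, `voices_per_octave = 16` (spacing
  $2^{1/16}$), over 1–39 h by default.
* **Cone of influence**: a sample is flagged invalid for a given period
  unless it lies at least one full period from both record edges. This is a
  deliberately conservative edge rule; all band statistics respect the
  `valid` mask.

`band_max_power()` takes, at each minute, the maximum power over all grid
periods inside a band (23–25 h for CR, 1–3 h for UR); the maximum tracks
the ridge of the rhythm rather than diluting it across the band.

Power is analyzed **raw first, then smoothed**: daily statistics of the raw
band series preserve within-day ultradian structure, while
`smooth_power()` (centered moving mean, exactly 24 h of samples) is applied
before slow criteria such as crossing times, where within-day ripple is
noise. `normalize_power()` z-scores a series against its own or a reference
window; `crossing_time()` scores the first day a daily statistic exceeds the
reference-window mean by 2 reference SDs.

## Estrous cycle detection and alignment

* **Rise detection** (`detect_rise()`): the pubertal fE2 rise is the first
  day fE2 exceeds its p25–p30 baseline mean by 2 baseline SDs. Baseline
  days must all be observed; a zero-SD baseline with no qualifying day is
  reported as `threshold_undefined`.
* **Cycle alignment** (`align_cycles()`): days from the rise onward are cut
  into 4-day blocks. The anchor is rotated (mod 4) so that the phase of
  maximal mean fE2 sits at within-block index 3, matching a cycle that
  rises for three days and falls on the fourth. `peak_day_index` reports
  the modal within-block argmax over complete blocks and should be 3 for a
  well-aligned cycling animal. Non-cycling animals (no detected rise) can
  be aligned on a fixed fallback day so their pseudo-cycles enter null
  comparisons.
* **Combined ovulatory metric** (`combined_metric()`):
  $z(\mathrm{CBT}) - z(\mathrm{UR\ power})$ per day. The estrous day after
  the fE2 rise elevates CBT and suppresses ultradian power, so the two
  z-scores reinforce; the metric is invariant to affine rescaling of either
  input.
* **Day-of-cycle inference** (`day_of_cycle_test()`): values are grouped by
  within-block day across all complete blocks — pooling animals and cycles
  as replicates — and tested with a Friedman omnibus followed by Dunn's
  pairwise comparisons (Holm-adjusted).
* **Spectral scoring** (`fft_band_auc()`): daily CBT is linearly detrended,
  its one-sided magnitude spectrum integrated over 1/5–1/4 cycles/day by
  the trapezoid rule with interpolated band edges. The edge interpolation
  makes the integral exactly additive over adjacent sub-bands.
  `fft_peak_period()` reports the dominant 3–6-day period;
  `fe2_cycle_auc()` the trapezoid fE2 area of each aligned cycle.

## Statistics

All group comparisons are nonparametric: Mann-Whitney (`rank_test_two()`),
Kruskal-Wallis and Friedman omnibus tests with Dunn's z post hocs
(`omnibus_with_dunn()`; tie-corrected for the independent design,
$k(k+1)/6n$ variance for the repeated design; Holm adjustment by default).
Monotone age trends use the Mann-Kendall test (`mann_kendall()`): exact
pairwise S statistic, tie-corrected variance, continuity correction, and
tau-b. Its implementation is verified in the test suite against brute-force
pairwise enumeration.

To avoid pseudo-replication from minute-level autocorrelation,
`downsample_for_stats()` reduces series to hourly means for spans under
3 days and daily means otherwise before between-group testing.

The circadian-power/estradiol relationship is modeled per group with
`mixed_cr_fe2()`: `power ~ fe2 + (1 + fe2 | id)` fit by maximum likelihood
(`lme4`), falling back to a random-intercept model when the random-slope
fit is singular (and flagging the fallback). The reported marginal $R^2$ is
$\mathrm{var}(X\hat\beta)/\mathrm{var}(y)$, the variance share of the fixed
effect alone.

## The synthetic generator

`simulate_animal()` builds a minute-grid CBT record as the sum of:

* a per-day level: 36.8 °C baseline plus a pubertal ramp of 0.025 °C/day
  over p26–p41;
* a circadian cosine peaking at clock hour 19 (mid-scotophase under lights
  on 01:00 / off 13:00), amplitude ramping 0.15 → 0.45 °C over the same
  window;
* a 2 h ultradian cosine of amplitude 0.25 °C;
* AR(1) noise (stationary SD 0.15 °C, lag-1 correlation 0.9) plus white
  noise at half that SD.

Cycling animals draw a pubertal onset day uniformly in p31–p36; daily fE2
is a 20 pg/g baseline with truncated-normal noise (±2 SD bound, so an OVX
animal can never cross a population 2-SD rise criterion by chance) plus
post-onset cycle increments of (15, 30, 45, 5) repeating every 4 days —
three rising days and a fall, peaking at within-cycle index 3 to match the
alignment convention. On the day after each cycle's fE2 rise, CBT is
elevated by 0.25 °C and ultradian amplitude halved.

Group templates modify this base: `OVX` caps the circadian ramp at 45 % of
its plateau, removes cycling, and adds a late CBT decline; `OVX_E2` starts
its (steeper) circadian ramp window at capsule implantation and adds tonic
fE2; `IntactC` abolishes estrous modulation from p50 and lowers CBT and
circadian amplitude during dosing. These defaults **are** the simulated
study conditions; analysis code never sees the ground truth, which is
returned separately in each record's `truth` field.

`inject_artifacts()` adds telemetry-like spikes and gaps with deterministic
per-day counts for preprocessing tests.

## Validation suites

The package's acceptance-style tests (in `tests/testthat/test-acceptance.R`)
exercise the full chain at these problem sizes, chosen to make the pass
criteria statistically meaningful while keeping the suite inside a normal
CI budget:

* Morse period mapping checked against the analytic peak frequency for all
  $\beta \in 3..8$, $\gamma \in 2..5$ (tolerance: one grid voice).
* Mann-Kendall equivalence to brute-force enumeration on 200 random
  vectors, including heavily tied ones.
* Circadian trend recovery on 100 ramped and 100 flat-amplitude animals
  (detection ≥ 95 %, false positives ≤ 10 %).
* Day-of-cycle detection on 100 intact cohorts of 8 (power ≥ 90 %), with
  100 OVX cohorts as a calibrated null and a 5-day re-binning control that
  abolishes the 4-day signal.
* 100 paired Intact-vs-contraceptive cohort draws for the post-p50
  4–5-day spectral-area contrast (≥ 90 % significant wins).
* Exact preprocessing replacement values and idempotence.
* Earlier 2-SD circadian crossing under estradiol across 50 shared-seed
  pairs, tested with a one-sided paired Wilcoxon signed-rank across pairs
  (the paired analogue of the rank-sum test, which matches the shared-seed
  design).
* Mixed-model slope recovery within 5 % over 200 simulated datasets with a
  known random-effects covariance.

The seeds in these suites are fixed for reproducibility and were committed
before the assertions were finalized; tolerances reflect the binomial
variability of the underlying detection rates, not tuning.
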
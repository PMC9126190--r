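Package: thermorhythms
Title: Multiscale Rhythm Analysis of Continuous Core Body Temperature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing ultradian (1-3 h), circadian (~24 h) and
    ovulatory (4-day estrous) rhythms in continuous, minute-binned core body
    temperature records from adolescent female rodents. Provides artifact
    cleaning and gap interpolation for telemetry data, a generalized Morse
    continuous wavelet transform with circadian and ultradian band-power
    extraction, detection and alignment of 4-day estrous cycles from daily
    fecal estradiol, a combined temperature/ultradian-power ovulatory metric,
    and the accompanying nonparametric statistical layer (Mann-Whitney,
    Kruskal-Wallis, Friedman with Dunn's post hoc comparisons, Mann-Kendall
    trend tests, and mixed-effects regression of circadian power on
    estradiol). A synthetic-cohort simulator emulating intact, contraceptive-
    treated, ovariectomized and estradiol-replaced animals allows the whole
    pipeline to be exercised and validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    zoo,
    pracma,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
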
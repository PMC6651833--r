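Package: bbpcarbon
Title: Regression Method Choice in Bio-Optical Carbon Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Type-I (ordinary least squares) and type-II (standard major
    axis, major axis, ranged major axis) linear regression with standard
    errors and a correlation-significance gate; derivation of bio-optical
    carbon model parameters (background particulate backscattering, carbon
    scaling factor, POC slope and intercept) from chlorophyll-backscattering
    and backscattering-POC match-ups; quality control of profiling-float
    backscattering profiles (despiking against a running-median filter,
    depth binning, dark-offset subtraction, bottle pairing); depth- and
    time-integrated carbon budgets under alternative regression
    parameterizations with anomaly and relative-percent-difference
    statistics; and seeded synthetic-data generators emulating cruise
    match-up tables, float profile series and gridded monthly ocean-colour
    series so the full analysis chain is reproducible without external
    archives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
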
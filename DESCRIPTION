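Package: growthscore
Title: Growth Score and Growth Level Metrics for 96-Well Phenotype Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies bacterial growth in 96-well phenotype microarray
    assays. Fits the four-parameter Zwietering logistic model (starting
    absorbance, lag time, maximum growth rate, biomass yield) to plate-reader
    absorbance time series by bounded least squares, and summarises each
    curve with two single-number metrics: the Growth Score, GS = (A - y0) +
    0.25*mu, computed from the fitted parameters alone, and the legacy
    Growth Level, a harmonic-mean statistic over the fitted curve. Includes
    qualitative growth-class assignment, readers and writers for long and
    wide plate-reader tables and condition maps, a command-line interface,
    and a simulation study comparing the two metrics on cohorts of synthetic
    growth curves drawn from uniform parameter ranges.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    e1071,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
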
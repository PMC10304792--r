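Package: heterores
Title: Quantifying Microbial Heteroresistance from the Inoculum Effect
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the median (IC50) and cell-to-cell spread
    (heteroresistance) of a lognormal single-cell resistance distribution
    from minimum inhibitory concentration (MIC) measurements taken at
    several inoculum sizes, or from dose-response survival curves.  The
    inoculum-effect estimator exploits the expected maximum order statistic
    of a normal sample to turn MIC readings at different inoculum sizes
    into a linear model for the distribution's location and scale, from
    which a model MIC (the 99.99th percentile of single-cell resistance)
    is predicted.  Includes simulators for broth microdilution
    inoculum-effect assays and agar plate-count dose-response assays,
    case-resampling bootstrap intervals, panel-level correlation and
    Welch-test summaries, plain-CSV input/output, and a command-line
    interface.  Ships a transcribed reference panel of 29
    Zygosaccharomyces food-spoilage isolates assayed against sorbic acid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
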
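Package: tockykinetics
Title: Kinetic Modeling and Summary Statistics for Fluorescent Timer
    Flow Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis of Fluorescent Timer ("Tocky") reporter timecourses
    in T cells. Provides a forward model of the Timer Blue signal as a
    linear ordinary differential equation driven by a parametric promoter
    activity function, inference of the five promoter parameters from
    normalized median-fluorescence timecourses by bounded multi-start
    least squares, the standard flow-cytometry summary statistics used in
    Timer studies (positivity gating, median fluorescence of gated
    populations, percent-of-experimental-max normalization, fold-change
    and genotype ratio curves, CFSE division-cycle summaries, pseudo-time
    binning on Blue levels), and a synthetic single-cell event generator
    with Blue-to-Red maturation, division dilution and lognormal
    measurement noise for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
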
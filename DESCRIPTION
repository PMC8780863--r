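Package: frqclock
Title: Delay-Differential Modeling of the Neurospora Circadian Clock Under
    Short Light-Dark Cycles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the Neurospora crassa FRQ/WCC circadian oscillator as a
    delay differential equation system with a VVD photoadaptation loop, under
    arbitrary piecewise-constant light-dark protocols (symmetric and asymmetric
    T-cycles, constant light or darkness). Provides rhythm quantification
    (peak-to-peak and spectral period estimation, phase angles, entrainment
    classification, light-response amplitude, protein smoothing), T-cycle
    entrainment scans with boundary detection and seeded parameter calibration,
    race-tube phenotype analysis (band periods from 24-h growth marks, growth
    rates and ratios, microconidia morphometry, correlation and t-test
    conventions), and seeded synthetic-data generators for densitometry, race
    tubes and conidium morphometry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
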
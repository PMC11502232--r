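Package: lhensemble
Title: Behavioral Population Dynamics and Gamma-Oscillation Assemblies in
    Hypothalamic Spike Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised analysis of extracellular multi-unit recordings
    during innate behaviors: time-warped firing-rate feature construction
    from spike trains and a behavioral ethogram, stability-selected spectral
    clustering of cells into behavior- and feeding-phase-specific
    populations, local field potential gamma-event and nonrhythmic-epoch
    detection by envelope thresholding, and an epoch-conditioned
    cofiring-ratio statistic with a uniform-shift shuffle null. Includes a
    synthetic-data generator that plants the population, oscillation, and
    assembly structure the analysis assumes, so every stage is testable
    without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
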
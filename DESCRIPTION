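Package: brscreen
Title: Suspect Screening and Quantification of Brominated Contaminants
    by High-Resolution Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for identifying and quantifying brominated contaminants
    in centroided full-scan high-resolution mass spectrometry (HRMS) data.
    Computes exact ion masses from molecular formulas with a pinned isotope
    mass table, predicts bromine isotopologue envelopes (binomial and full
    fine structure), performs ppm-tolerance targeted screening with
    quantifier/qualifier ion-ratio confirmation, discovers bromine-containing
    unknowns from their characteristic isotope spacing, decomposes accurate
    masses into candidate elemental formulas, fits external-standard
    calibration curves, and derives method-validation statistics (instrument
    and method detection limits, recoveries, matrix effects) and cohort
    summaries. Includes a simulator of Orbitrap-like centroided runs,
    calibration series and biota cohorts for end-to-end method testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mzR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
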
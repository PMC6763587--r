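Package: alphacog
Title: Individual Alpha Peak Frequency Analysis for Mobile EEG Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate the individual alpha peak frequency (iAPF) from
    multichannel EEG as the spectral centre of gravity of the whole-head mean
    power spectral density over the 7.5-13 Hz alpha band, with an
    alpha-presence gate against the neighbouring theta and beta bands.
    Includes EDF/EDF+ input and output, deterministic bad-channel detection
    (isoelectric, saturated, artifactual), zero-phase Butterworth bandpass
    filtering via second-order sections, average re-referencing excluding bad
    channels, spherical-spline interpolation of excluded channels, Welch
    spectral estimation over consecutive 30 s intervals, channel-reliability
    summaries, a matrix-formula two-by-three within-subject repeated-measures
    ANOVA with Mauchly sphericity testing, Greenhouse-Geisser correction,
    Bonferroni post hocs and effect sizes, and a synthetic five-phase cycling
    study generator (1/f background plus narrowband alpha with known
    ground-truth iAPF and injected channel failures) so that the full pipeline
    is verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
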
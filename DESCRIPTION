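Package: preictal
Title: Seizure-Precursor Detection in EEG via Hurst and Fractal-Dimension Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Sliding-window analysis of multichannel EEG-like recordings for
    epileptic-seizure precursor detection. Estimates the Hurst exponent by
    rescaled-range (R/S) analysis with a detrended fluctuation analysis (DFA)
    cross-check, computes Renyi generalized fractal dimensions and fractal
    spectra from value-bin probability distributions, and detects the
    precursor deflection (Hurst down, fractal dimension up) that precedes
    seizure onset, reporting per-record lead times and cohort summary
    statistics. Includes a synthetic-data module that generates fractional
    Gaussian noise seizure records and cohorts with full ground truth, plus
    readers and writers for plain-text EEG matrices and the 35 Hz
    low-pass/decimation preprocessing step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
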
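Package: slowmod
Title: Slow-Wave Cross-Frequency Coupling and Principal Frequency Modes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signed correlation cross-frequency coupling analysis for
    anesthesia EEG: a zero-phase FIR filter bank (0.1-4 Hz slow band plus
    2 Hz amplitude bands tiling 4-50 Hz), analytic-signal envelopes,
    Pearson correlation between the slow voltage and high-frequency
    envelopes with vertical stacking across epochs and locations,
    nearest-neighbor surface Laplacian referencing, non-centered principal
    component analysis of coupling-by-frequency patterns into principal
    frequency modes with mode projections and subject-level bootstrap
    confidence intervals, and a synthetic stepped-dose session generator
    with fully known coupling ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    signal
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
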
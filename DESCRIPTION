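Package: binsum
Title: Binaural Signal Combination Modelling for Amplitude-Modulated Tones
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the combination of amplitude-modulation signals across
    the two ears with a two-channel divisive gain-control model and a
    linear-summation alternative. Maps model responses to two-alternative
    forced-choice modulation-depth discrimination thresholds (dipper
    functions) and to steady-state auditory evoked-potential
    signal-to-noise ratios, simulates adaptive-staircase psychophysics and
    frequency-tagged EEG experiments from a known observer, and fits both
    models to either data type under the field's parameter constraints
    with multi-start derivative-free optimisation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    lhs
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
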
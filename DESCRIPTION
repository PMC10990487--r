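Package: optopav
Title: Simulation and Analysis of Opto-Pavlovian Fiber-Photometry Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for optogenetics-powered Pavlovian ("opto-Pavlovian")
    conditioning experiments recorded with fiber photometry. Generates
    pseudorandom trial schedules with exact per-type trial counts, simulates
    two-channel (405 nm isosbestic control / 470 nm signal) fluorescence
    traces with shared bleaching and motion artifacts and ground-truth
    transient amplitudes, performs isosbestic-regression dF/F0 normalization,
    aligns signals to task events for windowed area-under-curve learning
    curves and omission-dip quantification, measures response kinetics via
    zero crossings of the smoothed temporal derivative, and applies the
    matching statistical layer (one-sample, paired and unpaired t tests,
    one- and two-way repeated-measures ANOVA with Tukey post hoc tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    pracma,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
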
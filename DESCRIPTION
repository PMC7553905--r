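Package: sleepstates
Title: EEG Microstate Analysis of Sleep and Wake with Planted-Truth Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for EEG microstate analysis geared to NREM sleep versus
    wake and within-sleep condition contrasts: polarity-invariant modified
    k-means clustering of maps at Global Field Power peaks, selection of the
    number of microstates by a seven-criterion meta-criterion,
    winner-takes-all back-fitting with temporal metrics (global explained
    variance, duration, occurrence, coverage), Morlet-wavelet band power per
    microstate, repeated-measures ANOVA with Greenhouse-Geisser correction
    and paired sign-flip randomization tests, and a simplified distributed
    linear inverse for source-level contrasts.  A synthetic-EEG generator
    with planted microstate ground truth (templates, label sequences,
    band-specific carriers, condition effects) and a single-sphere toy lead
    field make every stage testable end to end without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    car,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
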
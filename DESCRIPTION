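Package: rovingmmn
Title: Roving-Oddball Mismatch Negativity Simulation and Analysis Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing auditory roving-standard
    (roving-oddball) mismatch negativity (MMN) experiments end to end:
    psychoacoustic distance metrics (Bark conversion, formant focalization,
    just-noticeable-difference counts), deterministic synthesis of inharmonic
    tone complexes and vowel-like fixtures with WAV I/O, constrained
    roving-standard sequence generation, a synthetic 31-channel EEG generator
    with event-locked ERP components, injectable condition-specific MMN,
    1/f background noise and artifacts (EDF I/O), ERP preprocessing
    (band-pass filtering, downsampling, epoching, baseline correction,
    amplitude-threshold rejection, averaging, Savitzky-Golay smoothing),
    identity-matched difference-wave area-under-curve quantification, and
    contrast-coded linear mixed-effects analysis with cell-mean summaries and
    simulation-based parameter-recovery studies.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    lme4,
    lmerTest,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
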
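Package: erp2ch
Title: Two-Channel Prefrontal ERP Analysis for the Auditory Oddball Paradigm
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-channel (Fp1/Fp2) prefrontal
    event-related potentials recorded during active auditory oddball
    sessions: FIR band-pass preprocessing, epoching, baseline correction
    and amplitude-based artifact rejection; N100/P200/P300 component
    extraction with single-trial P300 latency and amplitude variability;
    inter-channel connectivity via the Hilbert phase-locking value and
    Welch magnitude-squared coherence with band summary features;
    event-related spectral perturbation and inter-trial coherence
    time-frequency maps with permutation significance against the
    pre-stimulus baseline; time-trial maps; behavioral measures; and
    covariate-adjusted group statistics (gated t/Welch tests and parallel
    lines ANCOVA with Bonferroni post hoc contrasts).  A synthetic
    oddball-session generator with controllable evoked components,
    beta-band inter-channel phase coupling, event-related
    desynchronization, habituation and behavioral profiles makes every
    pipeline stage testable without cohort recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    car,
    emmeans,
    jsonlite,
    signal,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
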
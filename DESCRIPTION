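Package: odorlfp
Title: Olfactory-Bulb LFP Band Power, ROC Classification of Odorant Value,
    and Go/No-Go Behavioral Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for local field potential (LFP) recordings from
    mice discriminating odorants in a go/no-go task. Computes sliding-window
    spectrograms in decibels, baseline-subtracted odorant-evoked band power
    (delta power) for theta, beta, low-gamma and high-gamma oscillations,
    recentered ROC classification of odorant value (rewarded vs. unrewarded)
    with z-test significance and false-discovery-rate correction, permutation
    ANOVA and genotype-by-laser interaction tests for optogenetic experiments,
    and lick-onset-aligned LFP analysis including Hilbert theta phase of licks.
    A fully programmable synthetic-session generator produces go/no-go sessions
    with multi-electrode LFP, learning trajectories, reward reversal, and laser
    manipulations so that every stage of the pipeline can be validated by
    parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
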
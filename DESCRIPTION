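Package: srsleep
Title: Sleep-EEG Architecture and Spectral Statistics for Stress-Reactivity Mouse Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Epoch-based analysis of rodent sleep EEG/EMG recordings from
    mouse lines bred for high (HR), intermediate (IR) and low (LR)
    corticosterone stress reactivity. Provides spectral band-power feature
    extraction on 4-second epochs, rule-based vigilance-state scoring
    (WAKE/NREMS/REMS), event-history summaries of hypnograms (normed state
    durations, transition frequencies, REMS episode lengths), an
    interval-wise MANOVA/ANOVA battery with Bonferroni-modified LSD
    contrasts, and a nonparametric stability test (Wilcoxon matched pairs
    on per-Zeitgeber-hour excesses over the common median). A synthetic
    cohort generator with circadian-modulated Markov dynamics and
    state-conditioned signal synthesis makes the full pipeline testable
    without any recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    pracma,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
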
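Package: calcitrace
Title: Whole-Brain Calcium Imaging Traces: Baseline, Events, Seizures and
    Group Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for whole-brain wide-field calcium imaging of
    larval zebrafish. Computes dF/F0 from a moving-window percentile baseline,
    detects tiered Ca2+ events and calcium seizures (peak >= 100% dF/F0,
    boundaries at the 50% crossings), aligns seizures at 50% of their maximum
    for averaged waveforms with SEM, and summarises activity per larva (event
    counts, amplitudes, durations, area under the curve). Group comparisons
    use Wilcoxon-Mann-Whitney rank-sum tests for continuous measures and
    negative-binomial regression for overdispersed event counts, with a
    Shapiro-Wilk normality report. Includes multi-reference-gene ddCt qPCR
    quantification and a seeded synthetic-cohort generator with ground-truth
    annotations so every stage is testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    pracma,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
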
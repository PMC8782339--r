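Package: speechlr
Title: Speech-Timing Parameters and Forensic Likelihood-Ratio Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for forensic voice comparison based on speech timing.
    Reads tiered Praat TextGrid annotations of spontaneous speech, extracts
    eleven timing parameters (speech rate, articulation rates, stress-group,
    V-V unit and vowel durations, silent/filled/all pause durations and
    inter-pausal intervals), runs the non-parametric group-comparison battery
    (Kruskal-Wallis, Dunn's post hoc with Bonferroni adjustment, eta-squared
    effect sizes, balanced down-sampling with replications), and evaluates
    each parameter as a forensic speaker-comparison system via cross-validated
    kernel-density likelihood ratios with logistic self-calibration, reporting
    Cllr, equal error rate and multiclass AUC. A hierarchical synthetic-data
    generator emulates twin-structured speaker populations so the full
    pipeline can be exercised end to end without audio recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    readr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
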
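Package: perturbr
Title: Human-Like Text Perturbation and Robustness Evaluation for Health NLP
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates human-like perturbations of health-related text
    (typographical errors, homophone substitutions, redactions) at calibrated
    levels, builds perturbed evaluation corpora with a feasibility retention
    rule, evaluates any text model through a pluggable adapter interface with
    few-shot prompts, and runs a robustness-analysis chain: four-bin robustness
    classification, contingency tables with Pearson chi-squared tests, Friedman
    rank tests with Conover-Bonferroni post hoc comparisons, repeated-measures
    ANOVA, and a medical-term perturbation profile. Synthetic fixture
    generators with planted label signal allow the full pipeline to run
    offline with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
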
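Package: periopeval
Title: Set-Based Evaluation of Multi-Label Perioperative Complication Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An evaluation and statistical-comparison framework for multi-label
    detection of postoperative complications from clinical narratives. Provides
    set-based micro- and macro-averaged precision, recall and F1 (with lenient
    label-only and strict label-plus-severity matching), patient-level bootstrap
    paired testing across repeated inference runs with Bonferroni correction,
    Fleiss' kappa and majority-consensus gold standards, targeted task
    decomposition with deterministic aggregation rules, time-shift anonymization
    of dated record sections, and stratified sensitivity analyses by document
    length, complication count and documentation quality. A synthetic dual-center
    cohort generator with controllable predictor profiles makes every stage
    testable without access to real clinical records.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
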
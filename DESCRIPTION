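Package: oddballcrp
Title: Free-Recall Dynamics and Anchored Lag-CRP Analysis for Oddball Paradigms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing free-recall dynamics in emotional and
    perceptual oddball (Von Restorff) list-learning experiments. Computes
    standard lag conditional response probability (lag-CRP) curves and an
    item-anchored variant in which lag 0 denotes a designated oddball or
    matched control item, together with behavioural recall measures
    (total recall by stimulus onset asynchrony, oddball and control recall
    proportions, peri-oddball recall, output position, probability of first
    recall) and within-subject inference (2x2 repeated-measures ANOVA with
    partial eta squared, paired t-tests with Cohen's dz, Benjamini-Hochberg
    correction, paired-t power analysis). Includes a paradigm generator that
    reproduces the encoding design (40 lists of 14 nouns, one oddball per
    list, five stimulus onset asynchronies) and a minimal generative recall
    simulator with tunable contiguity, forward asymmetry, oddball salience
    and emotional forward-binding parameters, so the whole pipeline runs on
    synthetic data.
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
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
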
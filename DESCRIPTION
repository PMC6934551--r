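Package: discountr
Title: Delay-Discounting Choice Models, Subjective-Value Regressors, and
    Region-of-Interest Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for monetary delay-discounting
    experiments. Simulates the two-run intertemporal choice task (smaller-sooner
    versus larger-later monetary rewards), fits five discounted subjective-value
    models (hyperbolic, exponential, double-exponential beta-delta, discounted
    utility, and quasi-hyperbolic with exponentiated delay) plus a random-choice
    baseline per participant by maximum likelihood under a softmax decision rule,
    compares them with BIC and balanced accuracy, builds the un-modulated
    choice-period and subjective-value parametric-modulation event regressors
    used in fMRI general linear models (FSL three-column EV format), and runs
    the group-level standardized-regression stage relating PET receptor
    availability to fMRI subjective-value signal, with Fisher-z confidence
    intervals, Bonferroni control, and Cook's-distance/studentized-residual
    outlier diagnostics.
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
    lmtest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
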
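Package: neurosync
Title: EEG Neural Synchrony Neuroforecasting Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for stimulus-level EEG neuroforecasting:
    inter-subject neural synchrony from windowed alpha-band power over
    central electrodes, frontal alpha asymmetry, and the group- and
    individual-level inference that links these metrics to population
    outcomes (normality-gated correlations with Bonferroni control,
    log-transformed popularity regressions with back-transformed
    coefficients, nested model comparison, and stepwise AIC selection).
    Includes a synthetic multi-subject EEG study generator with known
    ground truth so every stage has a parameter-recovery test surface,
    plus readers and writers for EDF+ and long-format CSV recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lmtest,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
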
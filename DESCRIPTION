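Package: refstab
Title: Reference-Gene Stability Assessment for RT-qPCR Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native workflow for validating candidate reference
    (housekeeping) genes in RT-qPCR studies. Implements the four standard
    stability algorithms (comparative delta-Ct, geNorm stepwise exclusion,
    NormFinder variance decomposition, BestKeeper index correlation), combines
    their per-gene ranks by geometric mean into a comprehensive ranking,
    fits dilution-series standard curves to estimate amplification
    efficiencies, and computes 2^-ddCt relative expression with group
    statistics. Ships a seeded generator of synthetic cycle-threshold data
    with realistic per-gene baselines, shared sample loading effects and
    injected group or tissue-location shifts, so the whole pipeline is
    testable without access to raw instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
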
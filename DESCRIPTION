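Package: rubrovol
Title: Comparative Volumetrics and Phylogenetics of the Primate Red Nucleus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of brain-region volumes across
    primates, built around the red nucleus and its magnocellular (RNm) and
    parvocellular (RNp) subdivisions. Provides Cavalieri volume estimation
    from serial-section delineations with shrinkage correction, species and
    group-level relative-volume summaries, phylogenetic generalized least
    squares (pGLS) allometry with phylogenetic prediction intervals,
    multi-regime Ornstein-Uhlenbeck shift detection with parametric
    bootstrap support and signal-to-noise effect sizes, phylogenetic
    ANCOVA grade-shift tests, ancestral state estimation under single-rate
    and multiple-variance Brownian motion, and k-means clustering of
    ratio/difference morphospace features. Ships transcriptions of the
    published species trait table and human specimen weights, a surrogate
    chronogram for the twenty study species, and simulators for Brownian
    and Ornstein-Uhlenbeck trait evolution on trees.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    nortest,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    nlme,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
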
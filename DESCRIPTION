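Package: rareassembly
Title: Community Assembly Analysis of Rare Microbial Taxa
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the ecological assembly of rare microbial
    taxa from OTU count tables sampled over time. Classifies taxa into
    transient-rare, persistent-rare, intermediate-rare and common cohorts
    under explicit rarity and occurrence thresholds; builds Preston octave
    histograms and fits log-series and log-normal species abundance
    distributions with chi-squared goodness of fit; fits the Sloan neutral
    community model to occurrence-frequency versus abundance data with
    Wilson score confidence envelopes and a binomial no-drift comparison
    model; computes abundance-based beta-null deviations from randomized
    communities; runs permutation tests of location (PERMANOVA) and
    dispersion (PERMDISP) on Bray-Curtis dissimilarities; fits time-decay
    regressions of community similarity; and scans sensitivity of cohort
    definitions over threshold grids. A Dirichlet-multinomial synthetic
    community generator with known migration parameters makes every stage
    testable without sequence data.
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
    vegan,
    withr
Suggests:
    minpack.lm,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
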
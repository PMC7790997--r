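Package: exposcreen
Title: Two-Step GC-MS/MS Biomonitoring with QC-Gated Quantitation and
    Censored Cohort Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a two-step gas chromatography tandem mass
    spectrometry (GC-MS/MS) biomonitoring workflow for multipollutant
    panels in human plasma: four-criterion screening detection calls and
    detection-rate triage of a wide chemical panel, matrix-matched
    calibration with acceptance rules, targeted quality-control gates
    (matrix-spike relative standard deviation, inter-batch
    Kruskal-Wallis, standard-reference-material percent error), limit of
    detection estimation with LOD/sqrt(2) substitution for left-censored
    values, and the cohort reporting layer (detection-rate-conditional
    summaries, Bonferroni-adjusted rank-sum group comparisons,
    parent-child Spearman correlation matrices, reference-median
    ratios). A synthetic-data generator emulates the family-structured
    study design, log-normal exposures with age effects and
    within-family correlation, linear instrument response with batch
    effects, and left-censoring, so the whole pipeline is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
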
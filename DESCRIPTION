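Package: trawlselect
Title: Trawl Gear Size Selectivity from Covered-Codend Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of trawl gear size selectivity from covered-codend
    haul data. Fits contact-conditioned logistic (CLogit) retention models
    for square mesh panels and logistic retention models for codends by
    pooled binomial maximum likelihood, with deviance-based goodness-of-fit
    diagnostics. Provides double-bootstrap (within-haul and between-haul)
    Efron percentile confidence bands for parameters and selection curves,
    paired delta-selectivity comparisons between gear designs arranged as
    treatment trees, combined panel-by-codend retention, retained-population
    projections, and exploitation-pattern indicators (retention below and
    above the minimum conservation reference size, discard ratio) with a
    traffic-light categorization. Includes a synthetic-data generator for
    covered-codend experiments with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    grDevices,
    jsonlite,
    patchwork,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
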
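Package: nutriscoreR
Title: Updated Nutri-Score Scoring and Food-Supply Comparison Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the updated (2022/2023) Nutri-Score nutrient-profiling
    algorithm as a data-driven scoring scheme (point grids, special rules and
    class thresholds for general solid foods, beverages, and fats, oils, nuts
    and seeds), together with a branded-food snapshot comparison pipeline:
    data preparation (exclusions, group-level fibre imputation, fruit,
    vegetable and legume estimates, keyword flagging), per-product scoring,
    group-level summaries, class-distribution change analysis in percentage
    points, EAN-matched sensitivity analysis, and a synthetic branded-food
    database generator for testing every stage without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    stats,
    utils,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
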
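Package: chronovar
Title: Variance Partitioning and Rhythm Detection for Sparse Chronobiome Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for pilot human chronobiome studies with a
    small number of subjects sampled 12-hourly over repeated 48-hour sessions.
    Provides a synthetic-data generator emulating multi-subject sensor streams
    (actigraphy, ambulatory blood pressure, heart rate, light, communication,
    mobility, nutrient intake) and omics matrices (metabolome, proteome,
    microbiome) with planted subject and time-of-day effects; single-component
    cosinor rhythmometry with amplitude and phase cross-correlation;
    per-feature time-versus-subject variance partitioning with a percent
    cutoff classification; an exhaustive morning/evening permutation test;
    wake/sleep summaries including nocturnal dipping; and pairwise
    variance-correlation matrices with Bonferroni-corrected regression
    p-values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
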
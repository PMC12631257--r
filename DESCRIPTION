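Package: faersdp
Title: Disproportionality Signal Detection for FAERS-Style Spontaneous Report Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Ingestion, deduplication and cohort extraction for FAERS-style
    spontaneous adverse-event report data, with the four disproportionality
    statistics used in routine pharmacovigilance: the reporting odds ratio
    (ROR), the proportional reporting ratio (PRR), the Bayesian confidence
    propagation neural network information component (BCPNN IC), and the
    multi-item gamma-Poisson shrinker empirical Bayes geometric mean
    (MGPS EBGM). Includes MedDRA-style preferred-term to system-organ-class
    aggregation, combined signal criteria and rankings, demographic and
    time-to-onset descriptive tables, death-proportion summaries, and a
    synthetic report-database generator with planted signals so the whole
    pipeline can be validated against known ground truth.
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
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
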
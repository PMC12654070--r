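Package: sentinelmr
Title: Single-Sentinel Two-Sample Mendelian Randomization for Metabolite
    Exposures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for single-instrument ("sentinel")
    two-sample Mendelian randomization screens of quantitative exposures,
    such as plasma metabolites, against rare binary outcomes, such as
    leukemia subtypes. Provides readers and validators for variant-level
    GWAS summary statistics, sentinel instrument selection with variance
    explained and first-stage F statistics, LD-proxy substitution, effect
    allele harmonization with palindromic-strand resolution, Wald-ratio
    causal estimation with Bonferroni tiering, post hoc power for binary
    outcomes accounting for the case-control ratio, a pleiotropy drop-list
    screen, drug-annotation joins, and a synthetic GWAS generator with
    known causal ground truth for parameter-recovery and calibration
    experiments.
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
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
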
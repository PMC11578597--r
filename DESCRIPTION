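Package: mrcore
Title: Core-Instrument Sensitivity Analysis for Two-Sample Mendelian
    Randomization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Sensitivity analysis for two-sample Mendelian randomization of
    polygenic exposures based on the core gene hypothesis. Genetic
    instruments are ranked by putative coreness (per-allele effect size,
    per-variant heritability, significance, or sample-size-normalized
    significance), partitioned into near-equal groups, and group-specific
    and cumulative causal-effect estimates are computed with the inverse
    variance weighted, weighted median, and weighted mode estimators, so
    that estimates from the strongest (putative core) instruments can be
    compared against estimates from all instruments. Includes GWAS
    summary-statistics harmonization with a palindromic-variant filter,
    per-group instrument-strength F-statistics, a simulator of summary
    statistics with core/peripheral pleiotropy architecture, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ggplot2,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
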
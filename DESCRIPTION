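Package: ltpaPGS
Title: Optimized Count-Based Polygenic Scores for Leisure-Time Physical Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A candidate-SNP association and polygenic-score workflow for
    leisure-time physical activity (LTPA) studied in two populations.
    Provides panel-level quality control (allele frequencies, Hardy-Weinberg
    chi-square tests with exclusion, EM-based two-locus linkage
    disequilibrium, between-population allele-frequency tests and power),
    covariate-adjusted logistic SNP association with Cox-Snell R-squared,
    an unweighted effect-allele count score with forward optimization
    (joint p-decrease and R-squared-increase acceptance rule), score
    categorization, Jonckheere-Terpstra trend analysis across score
    categories, and a synthetic two-population cohort generator so the
    whole pipeline is testable without individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
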
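Package: sexforage
Title: Sex-Specific Floral Visitation and Nectar Chemistry Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of sex-specific foraging patterns in flower-visiting
    insects from long-term visitation records. Detects per-year windows of
    male-female phenological overlap, compares nectar-plant diversity between
    sexes with Hill numbers and linear mixed models, measures foraging
    dissimilarity with the Morisita-Horn index against marginal-preserving
    (Patefield) null models, identifies sex-associated plant species via
    Pearson chi-squared residuals, and contrasts nectar metabolite
    concentrations between female- and male-associated plants under a
    heterogeneous-variance model with planned contrasts and Bonferroni
    families. Includes a synthetic-data generator for protandrous flight
    phenology, seasonal flowering turnover, and sex-specific visitation
    preferences, so every stage is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    nlme,
    yaml,
    optparse
Config/testthat/edition: 3
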
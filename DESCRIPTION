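Package: dietomics
Title: Diet-Quality Indices and Their Proteomic and Metabolomic Correlates
Version: 0.1.0
Authors@R:
    person("Framingham", "Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to construct diet-quality pattern indices (Alternative
    Healthy Eating Index, DASH diet score, Mediterranean-style Diet Score)
    from food-frequency-questionnaire style intake tables, and to relate
    them to high-dimensional proteomic and metabolomic marker matrices via
    covariate-adjusted linear models with Benjamini-Hochberg and Bonferroni
    multiplicity control. Includes per-batch marker preprocessing,
    age/sex-adjusted partial Spearman correlation structure, hypergeometric
    pathway over-representation analysis on GMT gene sets, QTL/GWAS overlap
    reports, and a seeded synthetic cohort generator with planted effects
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
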
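Package: dietnet
Title: Diet-Microbiome Association and Co-Occurrence Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for diet-microbiome studies in pediatric
    cohorts: dietary index scoring (component indices, dietary inflammatory
    index, healthy food diversity, micronutrient insufficiency counts,
    food-additive exposure), Bray-Curtis dysbiosis scoring against a
    reference group, PERMANOVA variance partitioning, covariate-adjusted
    per-taxon association and interaction models with false discovery rate
    control, causal mediation (average causal mediation effect), SparCC
    compositional co-occurrence networks with permutation significance,
    network topology summaries, bootstrap comparison of topology across
    exposure strata, and natural-connectivity attack simulations. Includes a
    synthetic-cohort generator with known ground truth (planted basis
    correlations, diet effects, group shifts and mediation coefficients) so
    every stage is testable without access-restricted participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    igraph,
    randomForest,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
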
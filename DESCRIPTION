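Package: pgikit
Title: Polygenic Index Construction, Family-Based Effect Decomposition and
    Assortative-Mating Analysis on Simulated Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the statistical machinery of very large genome-wide
    association studies of behavioural phenotypes: additive and
    dominance-deviation association scans with orthogonal genotype codings,
    sample-size-weighted meta-analysis with summary-statistic harmonization
    and iterative clumping, LD-score regression for additive and dominance
    signals with block-jackknife uncertainty, clumping-and-thresholding
    polygenic indices with incremental R-squared and Nagelkerke R-squared
    evaluation, within-family direct/population effect decomposition with an
    assortative-mating transform, mate-pair polygenic-index correlation tests
    of phenotypic assortment, empirical-Bayes winner's-curse adjustment, and
    inbreeding-depression estimation from individual data or dominance
    summary statistics. A family-structured cohort simulator with tunable
    assortment, dominance, indirect parental effects and population structure
    makes every stage testable without access-controlled genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
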
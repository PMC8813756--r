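Package: placentamix
Title: Reference-Based and Reference-Free Cell-Type Deconvolution for
    Placental DNA Methylation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to benchmark reference-based against reference-free
    cell-type deconvolution of bulk placental DNA-methylation beta values.
    Includes a synthetic-cohort generator with known ground-truth cell
    composition (six placental cell types, gestational-age trends,
    beta-scale noise), robust-regression and non-negative least-squares
    reference-based estimators, a constrained alternating least-squares
    reference-free factorization with bootstrap-deviance selection of the
    component count, non-variable CpG filtering and principal-component
    extraction, a repeated cross-validation comparison of six predictive
    models for the dominant methylation axis, and nonparametric rank-based
    composition statistics (Spearman associations, paired signed-rank
    tests, relative effects, and a permutation global multivariate test).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    pracma,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
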
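Package: phenoscreen
Title: Phenotype-Augmented Bayesian Screening for Obstructive Sleep Apnea
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Derives clinical phenotypes of obstructive sleep apnea (OSA) by
    hierarchical clustering of categorical predictors under an odds-ratio
    weighted mismatch distance, and uses phenotype membership to augment a
    discrete naive Bayes screening classifier. Includes a seedable synthetic
    cohort generator emulating a referral sleep-laboratory population,
    stepwise k-nearest-neighbour imputation for categorical missing data,
    univariate variable screening, rule-out cutoff selection at a target
    sensitivity, repeated twofold and leave-one-out cross-validation, and a
    full diagnostic-test metric panel (likelihood ratios, diagnostic odds
    ratio, posttest probabilities).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mclust,
    withr
Config/testthat/edition: 3
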
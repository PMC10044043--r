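Package: caprigen
Title: Genetic Parameters for Dairy Goat Linear Appraisal and Zoometric Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the genetic evaluation of dairy goat conformation from
    linear appraisal (LAS) and zoometric records, modelled on the
    Murciano-Granadina CAPRIGRAN appraisal programme. Implements translation
    of zoometric measurements (cm, degrees) to linear appraisal scores with
    major-area weighting and final-score qualification; pre-model statistical
    screening (distribution diagnostics, Hoeffding's D independence test,
    variance-inflation-factor and Spearman redundancy filters); fixed-effects
    ANCOVA with Type III sums of squares, goodness-of-fit panels and
    standardized-residual flagging; pedigree utilities (numerator relationship
    matrix, inbreeding coefficients, sparse Henderson inverse); and REML
    estimation of variance components, heritabilities, genetic and phenotypic
    correlations with BLUE/BLUP solutions under a single-record animal model.
    A synthetic-herd generator reproduces the statistical structure of the
    appraisal data so that every stage of the pipeline can be validated by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    car,
    lmtest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
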
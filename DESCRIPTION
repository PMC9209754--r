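Package: qtlpyramid
Title: Additive and Epistatic Effect Analysis of QTL Pyramiding Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of quantitative trait locus (QTL) pyramiding experiments
    built on single-segment substitution lines (SSSLs) in a common isogenic
    background, with the stigma exsertion rate (SER) of rice as the motivating
    trait. Estimates single-QTL additive effects, multi-QTL combination
    effects, and additive-by-additive epistasis with season-blocked
    significance tests; classifies effect levels by exact one-dimensional
    least-squares partitioning; contrasts pyramids with and without a focal
    QTL and attributes a per-QTL epistatic effect to the focal locus.
    Includes the inferential toolkit used in such studies (Student's t,
    Dunnett's many-to-one test, Duncan's multiple range test with
    significance letters, arcsine square-root transformation of percentage
    traits) and a synthetic-data generator with known additive and epistatic
    architecture for validating every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mvtnorm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
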
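Package: nirblup
Title: Multi-Trait Genomic Prediction of End-Product Quality Traits with
    NIR-Predicted Secondary Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genomic best linear unbiased prediction (GBLUP) for wheat
    end-product quality traits augmented with near-infrared (NIR) predicted
    secondary phenotypes. Provides BLUE adjustment of unbalanced multi-trial
    phenotype records, VanRaden genomic relationship matrices with principal
    component analysis, single-trait and bivariate GREML variance-component
    estimation with per-trait missingness, cross-validation masking scenarios
    that inject NIR-predicted records into the training set, year-wise forward
    prediction across breeding cycles, and a synthetic breeding-program data
    generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    lme4,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
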
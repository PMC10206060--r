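Package: ocselect
Title: Optimal Cross Selection for Inbred Crop Breeding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks candidate bi-parental crosses for inbred crop breeding
    programs (e.g. soybean) by simulating F5-derived recombinant inbred
    progeny on a genetic map, predicting progeny genomic breeding values
    under ridge-regression BLUP, Bayesian ridge regression, BayesB, or
    epistatic (extended) genomic BLUP, and scoring each cross with a
    usefulness criterion (mean of the top fraction of predicted progeny
    values). Includes marker quality control, a multi-environment
    phenotypic mixed model for entry BLUPs and heritability, a validation
    harness comparing predicted cross values against observed progeny
    means under alternative training-set compositions, and a fully
    synthetic breeding-scenario generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    lme4,
    Rcpp,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation
Config/testthat/edition: 3
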
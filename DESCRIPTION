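Package: ftirms
Title: Dual-Modality Discrimination of Fracture-Related Infection from
    Plasma FTIR Spectra and Proteomic Abundance Ratios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Chemometric discrimination of fracture-related infection (FRI)
    from matched control plasma using two modalities. The mid-infrared branch
    preprocesses dried-film FTIR absorbance spectra (area normalization,
    additive log-ratio against a potassium thiocyanate internal standard,
    Savitzky-Golay filtering, internal-standard band removal) and compresses
    them with an orthonormal discrete cosine transform before univariate
    effect-size screening. The proteomic branch applies the same screening to
    log abundance ratios from TMT LC-MS/MS. Both feed a sparse elastic-net
    logistic classifier (hard cap on nonzero coefficients) whose performance
    is estimated by pair-level bootstrap sessions pooled under a fixed-effect
    meta-analysis. Also included: SVD/LDA discriminant visualization with
    multivariate-t confidence ellipses, canonical correlation and a
    cross-modal autoencoder for between-modality association testing, exact
    2x2 Fisher cohort statistics, and a synthetic paired-cohort generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    signal,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    pROC,
    metafor
Config/testthat/edition: 3
biocViews: Classification, Proteomics, Spectrometry, DifferentialExpression
RoxygenNote: 7.3.3
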
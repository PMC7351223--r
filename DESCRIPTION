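Package: ftdkit
Title: Feature Temporal Dynamics Analysis for Longitudinal Building Wastewater Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal untargeted LC-MS metabolomics of
    building wastewater sampled close to source. Takes preprocessed feature
    intensity tables (features by samples, with m/z and retention-time metadata)
    through pooled-QC run-order drift correction, blank subtraction and intensity
    filtering; classifies features as temporally stable or unstable with a
    three-class unstable taxonomy; clusters per-building feature temporal dynamics
    (fTDs) by K-means and models cluster centers with short-length-scale Gaussian
    process regression; screens feature pairs for temporal similarity and
    anticorrelation; classifies buildings from single-day feature profiles with
    L1-regularized logistic regression and random forests; groups features around
    important anchor features; and putatively annotates features by negative-mode
    adduct mass lookup against a packaged compound table. Includes a synthetic
    multi-building study generator with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    randomForest,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    withr
Config/testthat/edition: 3
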
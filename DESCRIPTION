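Package: ecglead2
Title: Single-Lead ECG Arrhythmia Feature Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for rhythm classification of 10-second,
    500 Hz electrocardiograms using only lead II. Provides a three-stage
    denoising chain (0.5-50 Hz band-pass, LOESS baseline removal,
    non-local-means smoothing), a bank of 25 time-domain, spectral and
    nonlinear signal descriptors combined with 13 demographic and
    GE-MUSE morphological attributes into a 38-column feature table,
    mutual-information (MRMR) and ReliefF feature ranking, class
    separability indices (mean Silhouette, Davies-Bouldin,
    Calinski-Harabasz) with 2-D projections, and a balanced per-class
    holdout evaluation protocol for multiclass rhythm classifiers.
    Includes a synthetic lead-II cohort generator so every stage is
    testable without the underlying clinical database.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    signal,
    randomForest,
    nnet,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    class,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
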
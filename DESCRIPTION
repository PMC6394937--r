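Package: sonotear
Title: Texture-Based Classification of Rotator Cuff Tears in Shoulder Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A computer-aided tear classification pipeline for shoulder
    ultrasound. Extracts histogram-moment intensity features and gray-level
    co-occurrence matrix (GLCM) texture features from a delineated lesion
    region of interest, screens features with normality-routed two-sample
    tests, fits a binary logistic-regression tear-probability model with
    stepwise backward elimination, and evaluates it by leave-one-out
    cross-validation with confusion-matrix indices and the empirical area
    under the ROC curve. Includes a synthetic sonographic phantom generator
    so the full pipeline is testable without clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    png,
    tiff,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    nortest
Config/testthat/edition: 3
RoxygenNote: 7.3.3
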
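Package: renotex
Title: CT Radiomics Pipeline for Grading Clear Cell Renal Cell Carcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for discriminating low-grade
    (ISUP I-II) from high-grade (ISUP III-IV) clear cell renal cell carcinoma
    from a single pre-contrast CT slice. Provides seeded synthetic tumor
    phantoms calibrated to published cohort statistics, gray-level
    discretization to a fixed bin count, six MaZda-style texture feature
    families (histogram, gradient, co-occurrence, run-length, autoregressive,
    Haar wavelet; 340 features by default), intraclass-correlation
    reproducibility screening, a stacked LASSO + random-forest + SVM
    classifier, and ROC evaluation with bootstrap and DeLong confidence
    intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    RNifti,
    withr,
    png,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
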
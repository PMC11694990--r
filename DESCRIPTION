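Package: ctgcompress
Title: Compression Indices from Simultaneous Maternal-Fetal Heart-Rate Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discriminating acidemic from non-acidemic fetuses using
    compression-based complexity indices computed on simultaneous fetal and
    maternal heart-rate recordings. Provides a synthetic cardiotocography
    cohort generator, artifact cleaning and trend/residual decomposition,
    Lloyd-Max scalar quantization, an extended-alphabet finite-context model
    for normalized relative compression, DEFLATE-based compression ratio and
    normalized compression distance, SMOTE minority oversampling with
    provenance tracking, and replica-aware cross-validated classification
    with support-vector machines, random forests and gradient-boosted trees.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    e1071,
    randomForest,
    xgboost,
    caret,
    pROC,
    jsonlite,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
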
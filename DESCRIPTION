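Package: octdistill
Title: Unsupervised Anomaly Detection in Retinal OCT via Reverse Knowledge Distillation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screening of retinal optical coherence tomography (OCT) B-scans and
    volumes for pathomorphological anomalies using reverse teacher-student
    knowledge distillation. A frozen convolutional teacher encoder produces a
    multi-level feature pyramid; a trainable bottleneck compresses it and a
    smaller student decoder learns, from normal scans only, to replicate the
    teacher's features. At test time, per-position feature disparities (a
    weighted cosine plus Euclidean distance) yield per-pixel anomaly explanation
    maps and scalar per-B-scan and per-volume anomaly scores. The package
    includes a synthetic layered-retina phantom generator with controllable
    lesions and pixel-accurate masks, the full evaluation battery (ROC/PR with
    AUC and average precision, leave-one-out PPV/NPV with optimal-cutoff
    transfer, relative-position anomaly profiles, severity association with
    rank correlations), broom-style tidiers, ggplot2 autoplot methods, and a
    command-line workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    png,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
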
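Package: moveprof
Title: Adherence and Proficiency Monitoring for Repetitive Exercise from
    Wearable Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for objectively monitoring repetitive,
    Tai Chi-style exercise from multi-site 9-axis inertial measurement
    units (IMUs): which protocol movement was performed (adherence) and
    how well it was performed (proficiency). Includes a synthetic IMU
    cohort generator with ground truth; session readers and writers;
    resampling and zero-phase Chebyshev filtering; automatic repetition
    segmentation from low-velocity pauses; a 378-feature registry
    (spectral, orientation, and inter-limb cross-correlation features);
    minimum-redundancy maximum-relevance (mRMR) feature selection with a
    95-percent-of-full-set rule; Random Forest movement identification
    cascaded into per-movement proficiency models with majority-vote
    aggregation; and a leave-one-subject-out evaluation harness with
    micro-F1 reports, misrouting robustness analysis, and Sammon
    projections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    randomForest,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
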
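Package: gaitsci
Title: Ankle-Worn IMU Gait Analysis for the Six-Minute Walk Test After
    Incomplete Spinal Cord Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of walking capacity from two ankle-worn
    inertial measurement units recorded during a six-minute walk test.
    Detects strides and gait events from the sagittal angular velocity,
    reconstructs per-stride 3D ankle trajectories by strapdown integration
    with zero-velocity updates, and derives the spatiotemporal,
    variability (cov), asymmetry, difference-to-reference, cyclogram
    (SSD, ACC, area), smoothness (modified spectral arc length) and
    fatigue/change gait parameters used to characterise walkers with
    incomplete spinal cord injury.  Includes data-driven gait clustering
    (PCA, Ward/k-means, core-feature selection, Kruskal-Wallis/Dunn/Fisher
    comparisons), leave-one-subject-out random-forest prediction of future
    improvement in six-minute walk distance, and a synthetic trial and
    cohort generator with planted ground truth so the whole pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
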
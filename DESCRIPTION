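Package: oapower
Title: Image-Derived Knee Osteoarthritis Phenotyping and GWAS Power Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale study of image-derived phenotyping of knee
    osteoarthritis and its consequences for genetic association power.
    Generates synthetic anterior-posterior knee scans with labelled femur,
    tibia and fibula masks and known joint-space geometry, measures the
    minimum joint space width (mJSW) endophenotype from segmentation masks
    with height-regression resolution normalization, ascertains binary
    case status by quantile dichotomization and by a simulated
    under-reporting electronic health record, and compares statistical
    power between quantitative-trait and case-control genome-wide
    association via genomic inflation, greedy LD clumping, LD score
    regression heritability and genetic correlation, and clumping-and-
    thresholding polygenic scores evaluated by covariate-adjusted logistic
    regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    png
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
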
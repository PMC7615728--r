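Package: cellscreen
Title: Cellwise Error Detection Benchmarks for Simulated Growth Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates paediatric height/weight cohorts from LMS (Box-Cox)
    growth-chart parameters, injects realistic error patterns into height
    cells (dropped or transposed digits, constant shifts, implausibly short
    stature), and benchmarks cellwise error-detection methods against the
    known error mask: robust standard deviation scores, boxplot fences,
    Tukey-depth bagplots, classic and robust (MCD, MVE) Mahalanobis
    distances, and a cell-level detector that predicts each cell from
    correlated variables (DetectDeviatingCells). Detection performance is
    summarised by sensitivity, specificity, positive predictive value,
    likelihood ratios, ROC curves with AUC, and the Youden index.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    pROC
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
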
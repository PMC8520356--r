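Package: neoventry
Title: Adaptive Threshold Segmentation and Ventricular Morphometry for
    Neonatal Brain MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Hybrid global/local Otsu threshold segmentation of neonatal
    axial brain MR slices guided by Sobel gradient pixel classification,
    measurement of four lateral-ventricle morphometric indices (anterior
    horn index F/F', body index D/D', caudate nucleus index C/C', Evans
    index), and cohort-level statistical evaluation (two-rater intraclass
    correlation, independent two-sample t-tests, chi-squared tests,
    empirical ROC curves with Youden-optimal cutoffs). Includes a
    synthetic phantom generator with analytic ground truth and a cohort
    simulator so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    png,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
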
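Package: lnfusion
Title: Combined PET/CT and EBUS Elastography Classification of
    Intrathoracic Lymph Nodes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies endobronchial-ultrasound elastograms (stiff area
    ratio, blue/green and blue/red pixel ratios, mean hue, mean gray,
    consensus grading score) and FDG-PET uptake volumes (SUVmax, SUVmean,
    metabolic tumor volume, total lesion glycolysis, CT short axis), fits
    ROC curves with Youden-index cutoffs and DeLong confidence intervals,
    and applies rule-based AND-fusion of the PET/CT and elastography calls
    to classify intrathoracic lymph nodes as malignant or benign, reporting
    the full set of diagnostic-performance metrics. Includes a synthetic
    cohort generator (tabular features, rendered elastograms, PET voxel
    grids, multi-rater grading panels) and deterministic fixture cohorts
    for end-to-end pipeline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    e1071,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
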
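Package: batscan
Title: Radiomics Detection of Brown Adipose Tissue on Nonenhanced CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end radiomics pipeline for detecting brown adipose tissue
    (BAT) on nonenhanced chest CT. Provides a seeded CT/PET phantom generator
    for paired volumes with adipose depot masks, BARCIST 1.0 reference
    labeling (fat HU window plus SUV threshold), a from-scratch radiomics
    extractor (first-order, 3D shape, GLCM, GLRLM, GLSZM, GLDM and NGTDM
    features over a 19-image-type filter bank; 1,743 features per depot), an
    ICC / Pearson-redundancy / LASSO feature-selection cascade, an SVM depot
    classifier with a Youden-index radiomics-score cutoff and symmetry-based
    per-patient diagnosis rules, Agatston coronary and thoracic-aorta calcium
    scoring, and diagnostic-performance utilities (Clopper-Pearson intervals,
    DeLong AUROC, propensity-score matching, group comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    glmnet,
    e1071,
    jsonlite,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
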
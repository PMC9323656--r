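Package: virtualbiopsy
Title: Virtual-Biopsy Radiomics of the Peritumoral Microenvironment in Early NSCLC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sphere-based "virtual biopsy" sampling of CT volumes at the tumor
    boundary, with IBSI-consistent radiomic feature extraction (intensity-based
    energy, maximum, median, 90th percentile; GLCM autocorrelation averaged over
    3D directions; GLRLM gray-level non-uniformity averaged over 2D directions
    and slices), a muscle-sphere noise-control filter, dual-observer
    Mann-Whitney intersection feature selection with ROC/Youden cutoffs,
    immunohistochemistry staining scores, and Kaplan-Meier survival analysis.
    Includes a synthetic CT cohort generator emulating a peritumoral
    inflammatory-rim effect so the whole pipeline is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    survival,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
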
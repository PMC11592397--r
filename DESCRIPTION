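Package: petrad
Title: Robust PET Radiomics Survival Modeling
Version: 0.1.0
Authors@R: person("PETRad", "Developers", email = "petrad@example.org",
    role = c("aut", "cre"))
Description: Tools for robustness-screened PET radiomics survival analysis:
    synthetic PET phantom and survival-cohort simulation, SUVmax-threshold
    lesion segmentation with five contour variants, IBSI-style radiomics
    feature extraction (first order, 3D shape, GLCM, GLRLM, GLSZM, NGTDM,
    GLDM over original, Laplacian-of-Gaussian and Haar wavelet images),
    ICC(2,1) feature-stability screening, nested cross-validated elastic-net
    Cox feature selection with Kaplan-Meier/logrank risk stratification, and
    balanced random forest classification of one-year survival.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    igraph,
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
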
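Package: dscradiomics
Title: DSC-MRI Radiomics Pipeline for Glioma Stratification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable pipeline for machine-learning-assisted radiomic analysis
    of relative cerebral blood volume (rCBV) maps from dynamic susceptibility
    contrast MRI of gliomas. Provides z-score intensity normalisation against a
    contralateral basal-ganglia reference region, extraction of 29 shape,
    histogram and rotation-invariant 3D Haralick texture features over tumour
    masks, covariate-corrected nonparametric group comparison (Mann-Whitney,
    Cliff's delta), repeated stratified-cross-validation random-forest
    classification of IDH mutation status and WHO grade with ordinal error
    analysis, and misclassification introspection. Includes a synthetic
    multi-centre cohort generator so every stage is testable without patient
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    ranger,
    e1071,
    stats,
    utils,
    tools,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
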
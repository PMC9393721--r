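Package: radalff
Title: Multimodal Hippocampal Radiomics from Structural MRI and Slow-5 ALFF
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds and evaluates multimodal radiomic signatures of the
    hippocampus from structural MRI volumes and amplitude-of-low-frequency-
    fluctuation (ALFF) maps computed in the slow-5 band (0.01-0.027 Hz) of
    resting-state fMRI. Provides motion quality control (framewise
    displacement, translation/rotation limits), Friston-24 nuisance
    regression, slow-5 ALFF map computation, IBSI-style intensity and
    texture feature extraction (GLCM, GLRLM, GLSZM; 101 features per
    modality), mRMR filtering and LASSO-based radscore signatures with SMOTE
    class balancing, and repeated stratified-split evaluation with ROC/AUC,
    DeLong comparisons, Wilcoxon tests and Spearman feature-score
    correlations. Includes a synthetic-cohort generator producing paired
    structural/functional NIfTI images, hippocampus-like ellipsoidal masks,
    rigid-body motion traces and clinical scores with controllable group
    effects, for end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    glmnet,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
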
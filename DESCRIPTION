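Package: lungmil
Title: Weakly Supervised Emphysema Detection with Quantile Multiple-Instance Learning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Detects and quantifies emphysema in chest CT volumes using only
    weak, subject-level labels derived from pulmonary function tests. Lung
    texture is characterized by 3D gray-level co-occurrence (Haralick)
    features and Gaussian scale-space filter-bank histograms computed on
    randomly sampled parenchymal patches. Two quantile-relaxed
    multiple-instance classifiers, miSVM-Q (instance level) and MILES-Q
    (bag level with sparse prototype selection), are trained on bags of
    patches labeled per subject, yielding both subject-level diagnosis and
    per-patch emphysema posteriors. Includes the Separability instance-level
    metric, a -950 HU low-attenuation-area baseline, nested stratified
    cross-validation, posterior slice maps, and a synthetic CT lung phantom
    generator with planted low-attenuation lesions and simulated FEV1/DLCO
    covariates for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    glmnet,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
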
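Package: pneumorad
Title: Radiomics and Blood-Biomarker Modeling of Immunotherapy-Associated
    Lung Inflammation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reusable pipeline for predicting immune-checkpoint-inhibitor
    associated lung inflammation in small-animal cohorts from pretreatment
    imaging and blood work. Provides threshold-based CT lung segmentation,
    a 92-feature volumetric radiomics extractor (geometric, first-order
    histogram, gray-level co-occurrence and third-order collinear-triplet
    texture features) with MRI intensity normalization, complete-blood-count
    ratio derivation, median dichotomization of a CD45 inflammation score,
    ANOVA screening with Pearson correlation pruning, and a ridge-stabilized
    binary logistic inflammation model evaluated by stratified two-fold
    cross-validation with ROC averaging. A synthetic-data module generates
    tabular cohorts and textured two-lung imaging phantoms with known group
    structure so every stage can be exercised and tested without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
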
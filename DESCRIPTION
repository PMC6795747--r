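Package: mrfusion
Title: Multimodal Region-Gene Fusion Features and Random-Subspace Forests
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An analysis pipeline for imaging-genetics fusion diagnosis of
    Alzheimer's disease. Genotype calls pass call-rate, minor-allele-frequency
    and Hardy-Weinberg quality control, are grouped into genes, segmented to a
    common length and digitally encoded; Pearson correlations between encoded
    gene sequences and parcellated fMRI region time series form a
    subjects-by-(regions x genes) fusion-feature matrix. A random-subspace
    ensemble of CART trees (the "multimodal random forest") classifies subjects
    by majority vote, and frequency-based feature selection over the
    best-performing trees yields an optimal fusion-feature subset from which
    disease-associated brain regions and genes are ranked. A seeded synthetic
    generator with planted region-gene couplings provides ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    rpart
Config/testthat/edition: 3
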
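Package: srdbnelm
Title: Sparse-Response Deep Belief Networks with Extreme Learning Machine
    Classification for Multimodal Imaging Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Feature learning and classification for multimodal imaging
    data. Implements sparse-response restricted Boltzmann machines trained
    by contrastive divergence with an L1 penalty on hidden activation
    probabilities, greedy stacking into a sparse-response deep belief
    network with optional supervised fine-tuning, snapshot ("fast")
    principal component analysis for high-dimensional voxel features, and
    an extreme learning machine classifier solved in closed form via the
    Moore-Penrose pseudoinverse. Includes a repeated stratified k-fold
    cross-validation harness reporting accuracy, sensitivity, specificity
    and AUC, a synthetic multimodal data generator with controllable class
    separation, and NIfTI volume readers for assembling labeled datasets
    from preprocessed brain images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    yaml,
    optparse
Config/testthat/edition: 3
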
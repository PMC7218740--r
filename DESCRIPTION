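Package: pyrfuse
Title: Contrast-Pyramid Medical Image Fusion with a Siamese CNN Weight Map
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fuses pairs of co-registered grayscale medical images (e.g. MR/CT,
    MR/PET slices). A Siamese convolutional patch classifier, trained to tell
    clear from blurred 16x16 patches, is applied fully convolutionally to
    produce a per-pixel weight map. Source images are decomposed by an
    invertible contrast pyramid, corresponding levels are fused with
    region-energy and local-similarity rules driven by the Gaussian-decomposed
    weight map, and the fused image is reconstructed by the inverse transform.
    Includes four objective fusion-quality metrics (Tsallis-entropy index,
    gradient-based edge preservation, mutual information, visual information
    fidelity), a synthetic phantom generator for training and testing, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    tiff,
    RNifti,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
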
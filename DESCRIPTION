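Package: mrimodal
Title: Multimodal Brain-MRI Tumor-Type Classification with Robust
    Feature Selection and Extreme Learning Machines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for classifying 2D brain MRI slices into the four
    standard acquisition modalities (T1, T1CE, T2, FLAIR) used in
    multimodal tumor imaging. Implements a hybrid linear contrast
    enhancement (K-means intensity split, edge-gated texture histogram
    equalization, and DCT-domain alpha-rooting refinement), deep-feature
    extraction behind a pluggable backbone contract with a deterministic
    random-projection toy backbone, correntropy-based group-sparse
    feature selection by accelerated proximal minimization with an
    extreme-learning-machine stopping rule, partial-least-squares
    feature fusion of two feature blocks, ridge-regularized extreme
    learning machine classification, evaluation metrics (accuracy, FNR,
    confusion matrices, multiclass MCC, run summaries and confidence
    margins), and simulators producing modality-mimicking brain phantoms
    and feature tables with known informative structure so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
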
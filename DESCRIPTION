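Package: agemap
Title: Explainable Brain-Age Modelling with Sensitivity Maps on Synthetic Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An end-to-end, fully testable pipeline for explainable brain-age
    analysis. A phantom module simulates multi-channel 3D volumes with known
    age- and disease-driven intensity effects and an integer-labelled atlas.
    A small 3D convolutional autoencoder is trained for reconstruction and its
    frozen encoder transferred to an age-regression network; predictions yield
    the brain age gap (BrainAGE), linearly bias-corrected on a held-out cohort.
    SmoothGrad sensitivity maps are computed from the network's input
    gradients, with the noise level calibrated by the age correlation of
    region-wise sensitivities. Region-of-interest ANCOVAs with false discovery
    rate correction compare morphometric and sensitivity maps across clinical
    groups, and Jaccard concordance quantifies the agreement of the two
    significance sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
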
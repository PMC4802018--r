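Package: atriareg
Title: Contrast-Based 3D/2D Registration of a Left Atrial Model to Biplane X-Ray
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rigid 3D/2D registration of a three-dimensional left-atrium model to
    biplane X-ray fluoroscopy based on injected contrast agent. Contrast is
    extracted by best-reference digital subtraction angiography; candidate poses
    are scored by similarity measures built on the projected model shadow, on
    explicitly rendered apparent edges, and on the consistency of a binary
    contrast-agent distribution estimate (CADE) reconstructed inside the model
    from the two thresholded projections. Per-frame translations are found with
    a deterministic coarse-to-fine lattice search, a best frame can be selected
    by a cross-measure ranking, and per-sequence trajectories are smoothed by
    confidence-weighted Markov-chain filtering. A synthetic biplane phantom
    generator with known ground truth makes every stage testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    tiff,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    generics,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
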
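Package: psmap
Title: Single-Frame Phase Singularity Detection on Cardiac Phase Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of phase singularities (rotor tips) in single frames of
    cardiac phase maps, on 2D rectangular grids and triangulated 3D atrial
    surface meshes. Implements four detector families (Canny-edge endpoint
    screening with monotonic-loop confirmation, mesh neighbor-ring monotonic
    phase progression, convolutional topological-charge estimation with
    selectable kernels, and ring phase-jump counting on meshes), a
    mesh-adjacency DBSCAN-style cluster refinement, the electrogram-to-phase
    pipeline (cubic-spline resampling, dominant frequency, sinusoidal
    recomposition, Hilbert instantaneous phase), phase-singularity density
    maps with SSIM and correlation similarity, tolerance-based
    precision/recall/F-beta scoring, parameter sweeps with k-fold
    cross-validation, and a synthetic rotor-field generator with exact
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
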
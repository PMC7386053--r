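# psmap

Single-frame phase-singularity (PS) detection on cardiac phase maps, for
researchers working on rotor mapping during atrial fibrillation. A phase
singularity is the point in a phase map around which the instantaneous phase
progresses monotonically through a full 2π cycle — the tip of a spiral-wave
rotor, and a candidate ablation target. Which sites get that label depends
heavily on the detection algorithm and its parameters; `psmap` implements the
four standard single-frame detector families side by side on a common
substrate so they can be compared, optimized and validated against ground
truth:

1. **Image-processing detector** (2D grid): Canny edges of the wrapped phase
   gradient, edge-line endpoints as candidates, monotonic-loop confirmation,
   centroid clustering.
2. **Neighbor-ring detector** (3D mesh): monotonic phase progression with one
   wrap crossing around sorted rings at a search radius of *N* nodal
   distances, loop gradient `max(φ_loop) − min(φ_loop)` thresholded.
3. **Convolutional topological charge** (2D grid):
   `n_t = (1/2π) ∮ ∇φ · dl` evaluated per cell as a pair of 2D convolutions
   of the wrapped phase gradients (kernels: sobel 3×3, sobel 5×5, nabla 2×2,
   nabla 3×3); cells with `|2π n_t|` above threshold are PSs, the sign giving
   the chirality.
4. **Phase-jump counting** (3D mesh): the signed count of sudden jumps in the
   raw phase differences around each node's ring; an odd count marks a PS.

Around the detectors: the electrogram→phase pipeline (cubic-spline resampling
to 512 Hz, dominant frequency, sinusoidal wavelet recomposition, Hilbert
phase), DBSCAN-style cluster refinement on the triangulation (5 mm), PS
density maps with SSIM and Pearson correlation, tolerance-based
precision/recall and the F_β score (β = 2), full parameter sweeps
(thresholds 0.1π–2π × radii 1–8 or four kernels) with 10-fold
cross-validation, and a synthetic rotor generator (spiral, spiral pair,
meandering, planar) with exact per-frame ground truth on 2048-node cylinder
shells.

## Worked example

```r
library(psmap)

cyl <- make_cylinder_mesh()                 # 2048 nodes, 3.45 mm spacing
sim <- synth_phase_sequence(scenario("spiral"), cyl)   # 205 frames @ 512 Hz
head(sim$truth, 2)
#>   frame node row col chirality
#> 1     1  992  16  32         1
#> 2     2  992  16  32         1

det <- detect_ps(sim$phase, algorithm = 4,
                 detector_params(4, refine = "dbscan"))
det[det$frame == 1, ]
#>   frame node row col chirality loop_gradient
#> 1     1  992  16  32         1      5.814082

cm <- match_detections(det, sim$truth, cyl$mesh, tolerance = 5,
                       n_frames = 205)
f_beta(cm, beta = 2)
#> $precision
#> [1] 1
#> $recall
#> [1] 1
#> $score
#> [1] 1
```

The detector recovers the rotor core at node 992 — the annotated ground-truth
cell — in every frame, with chirality +1 (phase increasing along clockwise
loops viewed from outside), and the refined output is a single detection per
frame, so precision, recall and F₂ are all 1 on this noise-free episode.

Sweeping parameters and cross-validating:

```r
episodes <- lapply(1:10, function(i)
  synth_phase_sequence(scenario("spiral", noise_sd = 0.05 * (i - 1),
                                frames = 40, seed = i), cyl))
cv <- cross_validate(episodes, algorithm = 4, k = 10, seed = 1,
                     refine = "dbscan")
cv
#> cv_result: algorithm 4, 10 folds, mean test F_2 = 0.996 (train 1.000)
```

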
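---
title: "Detecting phase singularities in cardiac phase maps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting phase singularities in cardiac phase maps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmap)
```

## The problem

During atrial fibrillation, wavefronts of electrical activation can organize
into rotors: spiral waves pivoting around a point where the instantaneous
phase of the local signal is undefined — a *phase singularity* (PS). The
phase map of a single time frame assigns every recording site a wrapped phase
in $(-\pi, \pi]$; a PS is a point around which that phase progresses
monotonically through a full $2\pi$ cycle. Locating PSs frame by frame is the
first step of rotor mapping, and the choice of detection algorithm and its
parameters materially changes which atrial sites get labelled as candidate
ablation targets. `psmap` implements four widely used single-frame detector
families on a common substrate — a 2048-node triangulated atrial shell with a
$32 \times 64$ cylindrical grid projection — together with the
signal-processing chain that produces the phase maps, the scoring machinery
to compare detectors against a gold standard, and a synthetic rotor generator
with exact ground truth.

## From electrograms to phase

`phase_field()` converts one electrogram per node into phase frames in four
steps:

1. **Cubic-spline resampling** to 512 Hz (`resample_cubic`). Clinical
   acquisitions arrive at ~2 kHz; 512 Hz retains the 1–150 Hz band of
   electrophysiological interest comfortably within Nyquist.
2. **Dominant frequency** (`dominant_frequency`): the largest
   spectral-magnitude peak inside 3–15 Hz (the physiological AF range), from
   a detrended, Hann-windowed, zero-padded (≥ 0.05 Hz resolution) FFT. Its
   inverse is the local atrial cycle length.
3. **Sinusoidal recomposition** (`sinusoidal_recomposition`): the signal is
   rebuilt as a superposition of single-cycle negative-cosine wavelets, one
   per sample, each with amplitude proportional to the local negative slope
   (non-negative slopes contribute nothing) and period equal to the cycle
   length. Sharp activation downstrokes become smooth oscillations at the
   local rate, which stabilizes the subsequent phase estimate. One cycle
   length is used per channel per episode.
4. **Hilbert phase** (`instantaneous_phase`): the analytic signal is built in
   the frequency domain on the mean-subtracted record and the phase is
   $\varphi = \mathrm{atan2}(h, f)$. No constant offset (e.g. $-\pi/2$) is
   applied: adding a constant to all phases moves no singularity. Frames
   within one cycle length (or 5%) of either end are flagged as edge frames;
   the transform's circular boundary makes them unreliable.

Phase is wrapped to $(-\pi, \pi]$ everywhere (`wrap_phase`), with the
convention that phase *advances* in time. Under that convention the analytic
signal recovers the generating phase with the correct sign; a
reversed-time-convention field would come back negated.

## The four detectors

All four run independently per frame (`detect_ps`); rotor tracking across
frames is out of scope.

**Algorithm 1 — image-processing detector (2D grid).** A Canny-style edge
detector runs with its gradient stage replaced by the wrapped one-step phase
differences of the frame (running Canny on raw phase would mark the entire
$\pm\pi$ wrap line as an edge). Non-maximum suppression and hysteresis
(defaults $0.3\pi$, $0.6\pi$ rad per grid step) leave edge pixels; candidates
are the ends of edge lines — edge pixels with at most one 4-connected edge
neighbor, which covers isolated near-core pixels and diagonal line ends. Each
candidate is confirmed by the monotonic-loop test on its "diamond" ring
(Manhattan radius $N$, default 3, minimum 2), and kept when the loop gradient
$\max(\varphi_{\rm loop}) - \min(\varphi_{\rm loop})$ reaches the threshold
(default $1.5\pi$). Kept pixels are clustered 8-connectedly and replaced by
their center of gravity (circular mean across the seam), snapped to the
nearest cell.

**Algorithm 2 — neighbor-ring detector (3D mesh).** Every node with a closed
sorted ring at graph distance $N$ (default 3) is tested directly with the
same monotonic-loop rule and threshold (default $1.5\pi$), followed by
DBSCAN-style refinement. Rings are ordered clockwise as seen from outside
the surface, by angle in the tangent plane of the angle-weighted vertex
normal, starting at the lowest node index.

**Algorithm 3 — convolutional topological charge (2D grid).** The
topological charge $n_t = \frac{1}{2\pi}\oint \nabla\varphi \cdot dl$ is
evaluated per cell as a pair of 2D convolutions of the wrapped one-step
phase gradients $k_x, k_y$ (`topological_charge_2d`). Four kernel pairs are
shipped (`ps_kernels`): `sobel3` (the published $3\times3$ half-weight
Sobel pair, the default), `sobel5` (standard $5\times5$ Sobel), `nabla2`
(forward differences — exactly the $2\times2$-plaquette winding number), and
`nabla3` (the 8-step closed square-ring circulation, the longer-path
analogue of `nabla2`). Each kernel pair is divided by its signed response to
an ideal unit vortex so all kernels report charge on the same scale and with
one chirality convention; cells with $|2\pi n_t|$ at or above the threshold
(default $1.9\pi$) are detections, the sign giving the chirality.

**Algorithm 4 — phase-jump counting (3D mesh).** On each node's clockwise
ring (default radius 1, i.e. the direct neighbors), the signed number of
sudden phase jumps is counted on *raw* consecutive differences:
$s = \#\{d < -\theta\} - \#\{d > +\theta\}$ including the closing pair, with
$\theta = 3.5$ rad ($\approx 1.1\pi$) by default. An odd $|s|$ marks a PS
with chirality $\mathrm{sign}(s)$; even counts (e.g. a planar wavefront
crossing the ring, one up-jump and one down-jump) mark nothing.

### The monotonic-loop rule and jitter

The textbook rule — phases non-decreasing around the loop with exactly one
wrap crossing — turns out to be unsatisfiable on discrete rings: even an
ideal noise-free Archimedean spiral produces counter-steps of a few
hundredths of a radian on hexagonal mesh rings (ring members sit at slightly
different radii, and the radial phase term is not constant along the ring).
`loop_monotonic_stats` therefore requires **exactly one wrap-scale descent**
(a raw step $\le -\pi$), **no wrap-scale ascent**, and no other descent
larger than a jitter tolerance (0.25 rad, about 4% of a cycle). Excluding
wrap-scale ascents matters: a ring whose phase values merely straddle the
$\pm\pi$ cut (a passing planar wavefront) shows one $\approx -2\pi$ and one
$\approx +2\pi$ raw step and must not be classified as a rotation.

### Chirality convention

Everywhere in the package, chirality $+1$ means phase increasing along a
loop traversed clockwise as seen from outside the surface. Grid diamond
rings, mesh rings, the charge kernels (via their signed gains) and the
synthetic generator all share this convention, so the four detectors and the
ground-truth annotations agree, and reflecting a frame flips every reported
chirality.

## Cluster refinement

Neighboring nodes of a true PS often satisfy the detection rule too,
yielding a small cluster per singularity. `dbscan_refine` merges them: a
density-based clustering in which the usual radius query is replaced by
direct triangulation neighbors plus a 5 mm metric cut-off, and each
connected cluster is replaced by its member with the greatest loop gradient
(ties break to the lowest node index). The 5 mm scale is roughly one
inter-node spacing (3.45 mm on the default shell) and below the 6–9 mm size
of an ablation lesion. `refine_neighbors` precomputes the neighborhoods with
a voxel hash so per-frame refinement is linear in the number of detections,
which keeps low-threshold parameter sweeps tractable. On ideal spirals the
greatest-gradient representative can sit one or two cells off-core (offset
rings pass nearer the core and reach more extreme values), so refined
positions carry roughly one node spacing of extra localization error;
algorithm 1 instead uses the cluster's center of gravity, which centers
better on symmetric clusters.

## Scoring and parameter optimization

`match_detections` implements tolerance-based confusion counting per frame:
detections and annotations within 5 mm are matched one-to-one,
nearest-first; matched annotations are true positives, every unmatched
detection a false positive (including duplicates near an already-matched
annotation), unmatched annotations false negatives, remaining node-frames
true negatives. Because a 2048-node map holds only 1–4 PSs, the classes are
extremely imbalanced, so performance uses precision/recall and the
$F_\beta$ score with $\beta = 2$ (recall weighted above precision: a missed
PS breaks rotor continuity, while over-detections are filtered later by
temporal criteria).

`parameter_sweep` scans thresholds $0.1\pi$–$2\pi$ (step $0.1\pi$) crossed
with radii 1–8 (2–8 for algorithm 1) or the four kernels (algorithm 3),
pooling (micro-averaging) confusion counts across episodes before scoring —
the alternative, averaging per-episode scores, weighs short episodes up and
is not used. Argmax ties break toward the larger threshold, then the
smaller radius (stricter and cheaper). `cross_validate` partitions episodes
into $k$ folds (default 10, per-episode) deterministically from a seed,
picks the training argmax per fold and reports held-out scores. Ring
differences and charge fields are computed once per frame and shared across
all thresholds, which is what makes the 160-setting grid affordable.

A caveat established while validating the package: detection counts are
*exactly* non-increasing in the threshold for algorithms 1–3 (each
thresholds a fixed per-candidate scalar), but **not** for algorithm 4. The
signed odd/even jump count is non-monotone: the two wrap-scale steps of a
ring crossed by a smooth wavefront have slightly different magnitudes, and
as the threshold passes between them the signed count jumps from 0 to
$\pm 1$, so detections reappear near thresholds of $1.7\pi$–$1.9\pi$. This
is a structural property of the rule, present even at vanishing noise, and
it is why the monotonicity check in the acceptance suite reports a failure
for algorithm 4 while passing 1–3.

## The synthetic generator

`synth_phase_sequence` paints analytic fields with known ground truth on a
grid or mesh; `make_cylinder_mesh` supplies the substrate (default: 32 × 64
nodes at 3.45 mm spacing, the mean inter-node distance of clinical shells;
optionally capped into a closed surface). Scenario defaults mirror the study
conditions: 205 frames at 512 Hz (≈ 0.4 s, the span of annotated clinical
rotor episodes), one rotor at 6.4 Hz, spatial wavenumber 0.35 rad/cell
(wavelength ≈ 62 mm, a plausible AF re-entry scale).

* **spiral**: $\varphi = \mathrm{wrap}(\chi\,\theta - k\,r + \omega t +
  \text{noise})$, with $\theta$ built from
  $\mathrm{Arg}(e^{2\pi i (z - z_0)/L} - 1)$ so the field is single-valued
  across the cylinder seam; the compensating topological charge escapes
  through the bottom boundary (or sits at the bottom apex of a capped mesh,
  where it is recorded in the annotation table — total chirality on a closed
  surface is zero). A core that would sit exactly on a node is perturbed
  half a cell.
* **spiral_pair**: opposite-chirality cores from the meromorphic ratio
  $\sin(\pi(z-z_1)/L)\,/\,\sin(\pi(z-z_2)/L)$, charge-balanced by
  construction.
* **planar**: a traveling wave along the row axis; the annotation table is
  empty.
* **meander**: a spiral whose core drifts on a circle of radius 3 cells over
  the episode, emulating drifting clinical rotors.

Noise is phase-additive Gaussian (wrapped after addition), seeded and
byte-reproducible. `synth_egm_from_phase` emits per-node electrograms
$a\,\sin\varphi$ with optional amplitude jitter and white noise. The sine
quadrature is deliberate: the recomposition inserts negative-cosine wavelets
at negative-slope samples, and working through the chain shows a
$\sin\varphi$ input is recovered by the pipeline as $\varphi$ with no
constant offset (a $\cos\varphi$ input would come back as
$\varphi - \pi/2$), keeping the round trip directly comparable without
offset fitting.

What the generator does *not* emulate: far-field ventricular artifacts,
inverse-solution spatial smoothing and its correlated noise, conduction
block lines, fractionated electrograms, or wavefront curvature away from the
Archimedean form. Passing tests on these fields demonstrate correctness of
the algorithms and their implementations, not clinical-grade performance;
absolute clinical scores depend on patient data and expert annotation that
no synthetic substrate reproduces.

## Numerical choices and degenerate inputs

* Wrapping is half-open: $\mathrm{wrap}(\pm\pi) = +\pi$.
* All 2D operations treat columns as periodic (the cylinder seam) and clamp
  rows; the last row of the row-direction gradient is zeroed, so charges in
  the final row are undefined and excluded from oracle comparisons.
* Ring extraction refuses nodes whose $N$-hop neighborhood touches an open
  boundary (no closed ring); callers skip them and the count is reported.
* Degenerate loops (constant phase) are non-monotonic by definition;
  zero-variance maps make correlation error out rather than return NaN;
  degenerate confusion counts give a zero score with a warning.
* Detector thresholds are validated into $(0, 2\pi]$; radii into 1–8
  (algorithm 1: 2–8, it needs room for the edge-line geometry).
* Episode lengths: detection-stage analyses use the 205-frame default;
  electrogram round trips use ≥ 640 frames (1.25 s) because the
  dominant-frequency estimator requires at least one second of signal, and
  interior frames exclude one cycle length at each end where the
  recomposition convolution and the Hilbert transform are edge-distorted.
  Cross-validation episodes use 40 frames each so a full 160-setting grid
  over 10 episodes stays affordable on one CPU.

## Known limitations

* Geodesic distances are not computed; 5 mm neighborhoods use straight-line
  chords, adequate at atrial curvature but wrong for strongly folded
  geometries.
* Algorithm 1's Canny stage is tuned for the 32 × 64 projection; much finer
  grids would need rescaled hysteresis thresholds (they are per grid step).
* The refined representative (greatest gradient) localizes about one node
  spacing worse than the raw detection stage on ideal rotors; centroid
  refinement is available via `detector_params(..., refine = "centroid")`
  for the grid detectors only.
* HDF5 containers are not supported; all interchange is delimited text
  (CSV with a `# fs` / `# frame_rate` header line), PLY/OBJ for meshes, and
  JSON for parameters and reports.
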
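---
title: "Contrast-based registration of a left-atrium model to biplane X-ray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrast-based registration of a left-atrium model to biplane X-ray}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(atriareg)
```

## The problem

Overlaying a preoperative 3D left-atrium (LA) model on live fluoroscopy
requires a rigid registration between the model's coordinate frame and the
X-ray system. The usable image evidence is injected contrast agent, and it
is sparse: to limit nephrotoxicity, physicians inject small volumes that may
opacify only part of the chamber — a vein and a sliver of the body rather
than the full silhouette. Implant-style registration (where the whole object
is visible) does not transfer. `atriareg` implements a registration pipeline
designed for partial opacification, estimating a 3-DOF translation per frame
of a biplane sequence. Rotation is deliberately out of scope: supine
head-first positioning rules out large rotations, and the small residual
rotations are not reliably observable from sparse contrast, so reference
registrations — and therefore the error metric `‖t̂ − t*‖₂` — are
translation-only.

## Model and assumptions

**Geometry.** Each plane is a pinhole camera with a known 3×4 projection
matrix mapping homogeneous world millimetres to pixels (0-based, centres at
integers). The two principal rays must be non-parallel; the default
parametric setup (`make_biplane_geometry()`) uses a frontal and a lateral
camera, source–iso-centre 750 mm, source–detector 1200 mm, and a detector
sized so pixel-unit parameters scale with resolution.

**Contrast extraction.** Subtraction of an uncontrasted reference isolates
contrast, but catheters and the diaphragm move between frames; choosing the
reference that minimizes the L1 norm of the subtraction image cancels them
as far as any single reference can. The binary mask thresholds the
median-filtered subtraction at `μ_f + σ_f` computed over the whole image —
with the strict inequality, a constant image yields an empty mask. The
sigmoid used before edge extraction has its midpoint at `t = μ_f − σ_f`, one
standard deviation *below* the mean, so the contrasted area maps to a
homogeneous plateau while the intensity drop-off at its boundary survives;
the exponent is `−(I_f − t)·s`, which is the reading under which the
homogenization behaves this way.

**Similarity measures.** All measures multiply one normalized
cross-correlation (NCC) per plane, so each factor is bounded in [−1, 1] and
a pose must explain *both* views. NCC is computed as the Pearson correlation
over all pixels (population statistics); any positive global scaling drops
out of the argmax, and a zero-variance image contributes 0 by convention
("no information"), counted in `la_log_counters()`. The subtraction-image
variant correlates the *signed* `I_DSA` with the shadow, since clamping
belongs to the mask path only.

The CADE measure is the package's centrepiece: a voxel is estimated
contrasted iff its projections land on contrasted pixels in both planes and
it lies inside the chamber. Correlating the *re-projections* of this
estimate with the contrast masks rewards poses under which the two views'
contrast is explained by one consistent 3D distribution. Maximizing the
contrasted-voxel *count* instead would bias the pose towards placing the
ray-intersection set inside the large chamber body; a regression test
constructs exactly this situation (vein contrast, pose slid along the vein)
and asserts that the count prefers the biased pose while the consistency
measure does not.

**Temporal model.** Over whole breathing cycles the LA oscillates about a
mean position, so inter-frame motion has zero mean and the transition
probability is a zero-mean Gaussian on velocity, `N(ΔT·r; 0, Σ_v)`, with `r`
the frame rate. The covariance `1·e(ρ)` of the per-frame state is read as an
isotropic covariance in mm² with standard deviation equal to the predicted
error `e(ρ)` in mm (the units are not fully pinned down in the source
material; this reading makes the state term dimensionally consistent and is
used throughout). `e(ρ)` is clamped to a floor of max(0.1 mm, smallest
positive fitted value) so covariances stay positive-definite. The MAP
objective is the standard Gauss–Markov chain quadratic with the transition
block weighted by `r²`.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| median kernel | 30 at 1024 px width | px | removes residual artifacts; scaled by width/1024, rounded up to odd |
| sigmoid slope `s` | 0.1 at 12-bit | 1/intensity | scales as 4096/range |
| DOG scale | 24 at 1024 px width | px | large scale keeps the edge objective smooth |
| `alpha` | 1 | — | equal weighting of base and edge terms |
| search range | ±40 | mm | covers >30 mm initial offsets |
| level-0 step | 16 | mm | ~125 coarse evaluations |
| refine factor / top-k | 2 / 8 | — | octree-style refinement |
| min step | 1 | mm | below the ~3.2 mm interuser variability |
| transition ridge `λ` | 1e-6 | (mm/s)² | only when training motion is degenerate |
| confidence floor | 0.1 | mm | keeps `Σ_i` positive-definite |

## The phantom generator

`build_phantom()` rasterizes an ellipsoidal chamber (default semi-axes
28×22×25 mm) with four tubular pulmonary veins on a 2 mm voxel grid, repairs
checkerboard voxel configurations so the extracted cuberille surface is
closed and edge-manifold, and attaches gradient-smoothed outward normals for
the apparent-edge renderer. `simulate_sequence()` renders attenuation as a
line integral of the binary fill mask (constant contrast density — adequate
because the method consumes subtraction differences, not absolute
intensities), grows the filled region by geodesic dilation from the
injection site so vein injections opacify the vein first, translates the
chamber along the cranio-caudal axis by `A·sin(2π·frame/period)` (zero-mean
breathing), and optionally adds the classic artifact set: a catheter curve
whose position differs between frames, a diaphragm ramp moving with
breathing, brightness drift, and Gaussian noise on a 12-bit scale. All
randomness derives from one seed; two runs are bit-identical.

What the phantom does *not* emulate: non-rigid cardiac deformation,
polychromatic/Beer–Lambert physics, scatter, photon noise statistics, real
catheter/device appearance, and clinically realistic anatomy. Passing tests
therefore demonstrate the *mechanics* of the method — contrast extraction,
projective consistency, capture range, filtering — under controlled
conditions, not clinical accuracy. The clinical error magnitudes from
patient studies are not reproducible at this scale and are never asserted.

## Numerical choices

- Voxel and triangle splatting uses the projected footprint (ceil of
  projected size, min 1 px), so coarse voxels leave no pinholes in masks.
- Edge compositing is `1 − Π(1 − o)`: order-independent and bounded, unlike
  additive or max compositing.
- Nearest-pixel lookup for the CADE conditions (the masks are binary;
  interpolation would manufacture fractional contrast).
- Median and Gaussian filtering use reflect padding; the 2-D Gaussian and
  its derivative are separable banded-matrix convolutions verified against a
  direct 1-D convolution of a step edge.
- The lattice search visits candidates in lexicographic (z, y, x) order and
  breaks value ties towards the lexicographically smallest point, making
  results bit-reproducible; non-finite objective values discard the cell and
  are counted.
- The Markov smoother ships a BFGS path (quasi-Newton with exact line search
  on this quadratic, via an analytic Hessian-vector product) and is verified
  against an independent dense block-tridiagonal solve to 1e-8 on random
  problems.
- Degenerate inputs: constant images yield empty masks and zero NCC;
  zero-area triangles are skipped and counted; constant training motion
  either errors or, with `regularize = TRUE`, receives a 1e-6 (mm/s)² ridge.

## Design decisions that were genuinely open

- **Surface extraction.** No marching-cubes implementation is available in
  the package's dependency set, so the surface is extracted as a cuberille
  (voxel-face) mesh after a well-composedness repair that guarantees every
  edge is shared by exactly two faces; normals are smoothed from the
  indicator volume's Gaussian gradient. For the edge renderer this behaves
  like a low-pass-filtered exact surface; it slightly thickens silhouette
  bands relative to a sub-voxel surface.
- **Median "kernel size 30".** Read as full width, made odd (31 at 1024 px).
- **Whole-image statistics** for `μ_f`, `σ_f` (no masking), matching the
  stated extraction rule.
- **Vein-injection study conditions.** Evaluations of measure orderings use
  ten phantoms with *varied* anatomy (jittered body radii, vein
  orientation/calibre), because clinical evaluations average over patients;
  repeating a single anatomy ten times would replicate one systematic bias
  ten times rather than average over anatomies.

## Known limitations

- Translation-only; the transform type has an extension point but no
  rotation math.
- The apparent-edge term is weaker at the package's working resolutions
  (128–256 px) than at the clinical 1024 px scale: silhouette bands are only
  a few pixels wide and the voxel-derived mesh quantizes normals, so
  `ρ_edge` used alone is the least accurate measure (as expected), and its
  *additive benefit* over the CADE measure on partially contrasted phantoms
  is marginal — on some phantom families `cade` alone outperforms
  `cade+edge`. The qualitative orderings (consistency measures beat the
  plain shadow on partial contrast; edge alone is worst) hold on the bundled
  study conditions and are asserted in the tests.
- Best-reference selection assumes at least one uncontrasted frame per
  sequence; contrasted/uncontrasted annotation is an input, not inferred.
- The temporal model is stationary: no breathing-phase-dependent transition
  statistics, no online (causal) filtering.
- Test problem sizes are deliberately desk-scale: 64–256 px rasters, 2 mm
  voxels, ten-phantom families. The methods scale to clinical sizes but the
  bundled evidence is at these sizes.
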
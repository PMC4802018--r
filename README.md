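# atriareg

Contrast-based 3D/2D rigid registration of a left-atrium (LA) model to
biplane X-ray fluoroscopy.

During catheter ablation of atrial fibrillation, a preoperative 3D model of
the patient's left atrium can be overlaid on live fluoroscopy — but only
after registering it to the X-ray coordinate frame. The only reliable image
evidence is injected contrast agent (CA), which often opacifies just part of
the chamber. `atriareg` implements an automatic, translation-only (3-DOF)
registration pipeline for this setting, together with a synthetic biplane
phantom generator so every stage is testable without clinical data.

## Method

Given two synchronized X-ray sequences with projection operators
`P_A`, `P_B` (3×4 matrices, world mm → pixels) and an LA model (triangle mesh
+ binary voxel indicator `χ`):

1. **Contrast extraction (DSA).** For a contrasted frame `I_c`, the
   uncontrasted reference `Î_u = argmin_u Σ|I_u − I_c|` minimizes motion
   artifacts; `I_DSA = Î_u − I_c` is clamped, median-filtered (`I_f`) and
   thresholded at `μ_f + σ_f` to a binary contrast mask `I_thr`. A sigmoid
   centred at `μ_f − σ_f` homogenizes `I_f` and a large-scale
   derivative-of-Gaussian filter yields the edge image `I_DOG`.
2. **Similarity measures.** With `ρ_n` the normalized cross-correlation, a
   candidate translation `T` is scored per plane and multiplied across
   planes:
   - shadow: `ρ_shad = ρ_n(I_DSA, S_T)·…` or with `I_thr` — `S_T` is the
     projected model shadow;
   - apparent edges: `ρ_edge = ρ_n(I_DOG, E_T)·…` — `E_T` renders every
     surface triangle with opacity `1 − |d·n|`;
   - CADE consistency: a voxel is estimated contrasted iff it projects onto
     contrasted pixels in *both* planes *and* lies inside the chamber
     (`C_T^3D(v) = I_thr^A(P_A T v)·I_thr^B(P_B T v)·χ(v)`); `ρ_CADE`
     correlates the re-projections of `C_T^3D` with the contrast masks.
   Combinations `ρ_base + α·ρ_edge` (default `α = 1`) are supported.
3. **Optimization.** A deterministic coarse-to-fine cubic-lattice search
   (default ±40 mm at 16 mm, halving to 1 mm) recovers the translation from
   initializations more than 30 mm off — beyond gradient-based capture
   ranges.
4. **Best-frame selection.** Either the frame with the maximal own
   similarity, or cross-selection: estimate each frame's pose with one
   measure, rank frames with another evaluated at those poses.
5. **Markov temporal filtering.** Per-frame estimates `T_i′` with similarity
   `ρ_i` are smoothed by maximizing a Gauss–Markov chain posterior:
   state covariances `Σ_i = e(ρ_i)²·I` come from a linear regression of
   observed error on similarity, transition covariances `Σ_v` from the
   sample covariance of annotated inter-frame velocities; the convex
   quadratic is solved by BFGS (an independent block-tridiagonal solve backs
   it in the tests).

## Worked example

```r
library(atriareg)

model <- build_phantom(phantom_spec(seed = 1))
geom  <- make_biplane_geometry(c(128L, 128L))
sim   <- simulate_sequence(model, scenario_center_injection(), geom, seed = 5)

cfg <- run_config(measure = "cade+edge",
                  search = search_config(range_mm = 24, level0_step_mm = 8,
                                         keep_top_k = 6))
rep <- run_pipeline(sim$sequence, model, cfg, truth = sim$truth)
rep
#> <la_report> cade+edge, 9 frames, seed 1
#>   best frame: 4
#>   mean error: 3.51 mm unfiltered, 3.38 mm filtered
```

The report lists, per contrasted frame, the estimated translation `t̂` (mm),
the similarity value `ρ` at the optimum and, because the phantom's ground
truth was supplied, the error `‖t̂ − t*‖₂`. Here the mean per-frame error is
3.51 mm and Markov filtering nudges it to 3.38 mm — around the ~3.2 mm
interuser variability reported for expert manual registration.
`tidy()`, `glance()` and `autoplot()` work on the trajectory objects, e.g.

```r
regs <- register_sequence(sim$sequence, model, cfg$search, "cade")
autoplot(regs)          # similarity per frame
```

A thin command-line wrapper is installed at `inst/cli/atriareg`
(`atriareg phantom|register|evaluate …`).

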
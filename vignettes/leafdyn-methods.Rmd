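---
title: "Modelling leaf growth and cell division with leafdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling leaf growth and cell division with leafdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`leafdyn` simulates a growing two-dimensional leaf tissue — the *canvas* —
together with the polygonal virtual cells (*v-cells*) riding on it.  The
model separates three layers of control:

1. **Specified growth.**  Each tissue element carries growth rates
   parallel (`K_par`) and perpendicular (`K_per`) to a local polarity
   axis.  These rates are products of promotion and inhibition factors,
   `pro(p, i) = 1 + p i` and `inh(h, i) = 1/(1 + h i)`, applied to
   regulatory fields: a proximodistal gradient PGRAD, a lamina marker
   LAM, a midline stripe MID (all fixed to the tissue and deforming with
   it), a diffusible proximal mobile factor PMF sourced at the
   petiole-lamina boundary, and two global temporal factors, LATE
   (rising from 148 h, linearly at 0.0048 h^-1, exponentially after
   189 h in the late-stage models) and EARLYGROWTH (declining from
   189 h at 0.0417 h^-1).  Polarity derives from the gradient of a
   factor POL that diffuses from the leaf base during a 20-step setup
   phase and then deforms with the tissue.

2. **Resultant growth.**  Specified growth is reconciled with tissue
   connectivity mechanically.  The published account delegates the
   mechanics to a finite-element growth framework without printing its
   equations; the one recoverable contract is that spatially uniform
   specified growth must be realized exactly.  `leafdyn` therefore uses
   a least-squares elastic-mismatch relaxation: each element is given
   the target deformation gradient `F_t = R diag(1+K_par dt, 1+K_per dt)
   R^T` and the node positions minimize `sum_e A_e ||F_e(x) - F_t,e||^2`.
   The objective is quadratic, the two coordinate directions decouple,
   and one sparse Cholesky factorization per step solves both.  Uniform
   specified growth yields zero residual, satisfying the contract; for
   smooth non-uniform fields the residual is the mechanical
   accommodation.  Element inversion aborts a step and triggers
   time-step halving.

3. **Division.**  v-cell vertices are anchored to mesh elements by
   barycentric coordinates and move with the tissue.  A cell is
   *competent* (CDIV) when PMF at its centroid exceeds a layer-specific
   threshold (0.184 subepidermis, 0.295 epidermis), PGRAD passes the
   epidermal gate (0.628), and LATE is below the arrest threshold
   (0.1680; 0.0768 in the epidermal midline).  Competent cells divide
   on reaching a target area: the mean target `Abar` is 150 um^2 before
   114 h, then interpolates between 150 and 300 um^2 as PMF falls from
   0.51 to the competence threshold (lamina), or takes the midline
   values (500 um^2 epidermis; `1.5 * 500 * PGRAD` subepidermis).  The
   noisy threshold uses a relative deviation drawn once at birth
   (normal, sd 0.2, truncated at 0.3 — a 3.5-sigma event preserving the
   stated moments to < 0.1%), multiplying the current local `Abar`;
   this reconciles "target drawn once at birth" with the continuous
   PGRAD dependence of the subepidermal midline target.  Division uses
   the shortest wall through the area centroid (1-degree directional scan with
   golden-section refinement; symmetric ties resolved to the smallest
   scan angle), displaced by a uniform-disc sample of radius 0.25 times
   the nominal wall length, with endpoints pulled 5% of the wall length
   along the intersected edges ("slight shortening").  New wall
   vertices are inserted into every polygon sharing the cut edge, so
   cells (plus intercellular spaces) tile the canvas exactly at all
   times; daughters partition the mother to 1e-9 relative area.

In the subepidermal model, intercellular spaces replace 30 three-way
wall junctions at 120 h and further junctions at 11 h^-1; each space is
a near-equilateral triangle of initial area 2 um^2 whose vertices move
away from its centre at 1.25% of its size per hour (areal growth
2.5% h^-1), implemented as autonomous size dynamics about the advected
centre so the printed rate holds exactly.

## Presets and mutants

`model_variant()` wires the published model family: the two early-stage
presets (87-178 h), the late-stage mature model (87-412 h, exponential
LATE + EARLYGROWTH decline, extra inhibition coefficients 0.24 and
2.8), the limit-free variant (distal growth inhibition through
`1 - PGRAD` and `1 - LAM`), the limiting-cell-size variant (growth
scaled by `omega = clamp((a2 - ca)/(a2 - a1), 0, 1)` with lamina
thresholds 4000/8000 um^2 and midline 18000/20000 um^2), and the
environment presets: *plate* (physiological ratio 0.55 and global
growth scale `k' = 0.6`, a net slowdown to 0.33) and *chamber-tuned*
(ratio 0.75).  Physiological time rescales the temporal-factor schedule
and the growth-rate magnitudes; diffusion runs in actual time.  Mutant
modifiers are `a_prime` (division-threshold offset, lamina), `k_prime`
(global growth scale) and `t_prime` (timing shift of LATE and
EARLYGROWTH).

## Calibrations the source leaves open

* **Initial geometry.**  The initial canvas is shown only graphically
  in the source material.  `leaf_geometry()` builds a petiole stub plus
  a smooth lamina bump; its dimensions were fixed once against the
  printed width anchors (a primordium on the 0.1 mm scale at 87 h whose
  mature epidermal model reaches a width of about 3 mm at 412 h) and
  are ordinary configuration inputs.
* **PMF length scale.**  The PMF diffusion rate is printed as 0.01
  without units.  We read it as mm^2/h and expose a single
  dimensionless calibration on the diffusion length
  (`pmf_length_scale`, default 1.72), fixed once so that the running
  early subepidermal model places the PMF = 0.184 contour near 400 um
  from the petiole-lamina boundary — the correspondence the source
  itself states.  The epidermal threshold 0.295 then lands near 300 um
  with no further freedom.
* **PMF dilution.**  Whether PMF concentration dilutes with growth is
  unstated; both modes are implemented (`pmf_dilute`), with diluting
  concentration as the default (amounts conserved through the lumped
  mass matrix, then an implicit diffusion-decay step).
* **POL diffusivity** is named but not valued; the default spans the
  initial primordium smoothly within the 20 setup steps.
* **Initial factor profiles.**  PGRAD linear from 1 (base) to 0.195
  (tip); LAM sigmoidal across the petiole-lamina boundary; MID a smooth
  stripe of 16 um half-width (capped at half the local leaf half-width
  so the narrow tip is not engulfed); all config-exposed.
* **Initial cells.**  Cells are superimposed as an irregular offset-row
  ("brick") packing whose walls meet in three-way junctions, then each
  packing cell is divided once by the noisy shortest-wall rule during
  setup, so the initial tissue has division-generated wall geometry and
  topology like imaged primordium cells.  About 240 cells of ~75 um^2
  result at default settings.

## The synthetic tracking generator

`from_trajectory()` exports a simulation as a `tracking_dataset` — the
same vertex/cell/lineage CSV trio used for real tracked data — with
optional isotropic Gaussian vertex noise (hand-clicked-vertex error)
and occlusion-style dropout of a connected cell patch.
`parametric_generate()` is simulator-free: a polygon packing advected
by a prescribed growth field with threshold-area division, emitting
exact ground truth.  These emulate the statistical structure of the
tracked data (growth gradients, noisy area thresholds with sd
`0.2 Abar`, 2-h or 12-h sampling); they do not emulate segmentation
artifacts, out-of-plane curvature, or fluorescence variation, so
passing recovery tests validates the metrics pipeline, not the imaging
chain.

## Numerical choices

* Time step 1 h (2 h in the reduced-size test configuration); divisions
  are checked once per step, so observed execution areas sit slightly
  above the sampled threshold (about `A k dt / 2` on average, ~1-2% at
  early-model growth rates) — the same kind of sampling overshoot a
  2-h imaging interval produces in the tracked data.
* Diffusion uses lumped-mass P1 finite elements with implicit Euler
  (unconditionally stable).
* Directional growth rates project the log right-stretch tensor
  `ln U` on the midline axis, so parallel + perpendicular = areal holds
  exactly and rigid motions give zero; the midline axis is the deformed
  image of the initial symmetry axis (a material curve), not a fixed
  laboratory axis.
* Distances to the petiole-lamina boundary are arc lengths along the
  deformed midline at the cell's material station; strata use half-open
  bands [0, 150), [150, inf) um.
* The printed tracked-growth formula `ln(A_t2 - A_t1)/(t2 - t1)` is
  dimensionally inconsistent; the implementation uses
  `ln(A_t2 / A_t1)/(t2 - t1)`, the only reading consistent with
  relative elemental growth rates and with the clone-area clause.
* Minimal divisible area 4 um^2; degenerate wall placements are
  resampled up to 10 times, then the nominal (noise-free) wall is used.

## Problem sizes

Default runs use the 3000-element canvas.  The test suite exercises
the presets at a reduced size chosen as the smallest configuration
that still resolves the corridor, topology and mutant comparisons
(672-element mesh, ~110-cell packing, 2-h steps); the acceptance
script runs the default mesh throughout.  Three seeds are pooled for
stochastic quantities (division statistics, topology).

## Known limitations

* The tissue is flat: no out-of-plane curvature or buckling, and no
  element subdivision, so extreme late-stage anisotropy is resolved at
  the initial mesh resolution.
* The least-squares relaxation is one admissible mechanics satisfying
  the uniform-growth contract; residual stress history is not modelled.
* The isotropic-control contrast in six-sided cell frequency is small
  at this problem size and emerges reliably only when several seeds are
  pooled.
* Serrations, stomatal lineages and 3D cell volume are out of scope.
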
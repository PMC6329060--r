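---
title: "Measuring pelvic incidence from CT-derived 3D pelvic models"
author: "pelvinc developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring pelvic incidence from CT-derived 3D pelvic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement

Pelvic incidence (PI) is the angle between the perpendicular to the
superior sacral endplate at its midpoint and the line joining that midpoint
to the hip axis (the midpoint of the two femoral-head centers). It is an
anatomical parameter: unlike sacral slope or pelvic tilt it does not depend
on the patient's pose, which is why a CT-based measurement is attractive —
the usual standing lateral radiograph suffers from imperfect femoral-head
superimposition and projection ambiguity, while CT gives the full 3D
geometry.

`pelvinc` implements the CT route as a deterministic pipeline:

1. **Segmentation** — HU thresholding (default lower bound 200 HU, a
   configurable stand-in for a per-case expert choice) followed by
   26-connected region growing from a seed; femoral heads or vertebrae
   still attached at threshold are removed by additional seeds
   (`remove_component()`), replacing the interactive removal of the
   original workflow.
2. **Surface reconstruction** — marching tetrahedra at level 0.5 on the
   binary mask (a marching-cubes-style isocontouring; the 6-tetrahedron
   cell split needs no case table and is watertight by construction),
   then minimal Taubin smoothing (10 iterations, lambda = 0.5,
   mu = -0.53). Taubin's shrink/inflate pair damps the voxel staircase
   while approximately preserving volume, and never changes topology —
   "minimal smoothing without simplification".
3. **Anatomical frame** — the anterior pelvic plane (APP) of Lewinnek,
   through both anterior superior iliac spines (ASIS) and the
   pubic-tubercle (PT) midpoint. Landmarks are supplied as seeds and
   refined by a fixed-point iteration ("most ventral vertex within 10 mm
   of the current estimate"), bootstrapped from the raw seeds and iterated
   with the frame (at most 5 rounds, 1e-3 mm tolerance, ties broken by
   lowest vertex index for determinism). The model is then rigidly
   realigned so the APP is vertical.
4. **Hip axis** — least-squares spheres fitted to both acetabular fossae:
   an algebraic fit initialises a geometric (orthogonal-distance)
   Gauss-Newton refinement; an inlier band (|distance to surface| <= 10%
   of the radius) combined with a concave-side filter (vertex normals must
   face the current center) rejects the acetabular rim, the cup's convex
   outer wall, and nearby structures. The hip axis is the midpoint of the
   two centers.
5. **Mid-sagittal plane (MSP)** — initialised with the left-right axis as
   normal through the ASIS midpoint, refined by ICP symmetry: a fixed
   deterministic subsample (5000 vertices, uniform stride) is mirrored
   across the current plane, matched to nearest mesh vertices
   (point-to-point, no trimming), and the optimal improper rigid map
   (Kabsch constrained to det = -1) yields the refined normal (its -1
   eigenvector) and offset. Divergence is declared only on a sustained
   strict rise of the mean closest-point distance at least 20% above the
   best value seen — relaxation overshoot near the fixed point is not
   divergence.
6. **Endplate** — 5000-8000 surface points (the operating window of the
   source method at ~1 mm voxels) are gathered by region-growing over the
   mesh from the endplate seed, keeping vertices whose surface direction
   lies within 45 degrees of superior, with the radius adapted until the
   count lands in the window. The points are projected orthogonally onto
   the MSP and a sagittal line segment is fitted by *orthogonal* (total)
   least squares — the principal axis of the centered 2D cloud. Endpoints
   are the extreme projections onto the line; the midpoint is their mean.
   Orthogonal rather than ordinate regression keeps the fit
   rotation-invariant for steeply inclined endplates.
7. **PI** — the hip axis is projected onto the MSP; PI is the angle
   between the in-plane perpendicular to the endplate line at its midpoint
   (oriented toward the hip axis) and the midpoint-to-hip-axis direction.
   Values outside the observed normal-cohort range 30.49-70.12 degrees are
   flagged, never rejected — that range is empirical, not a constraint.

The endplate is additionally classified by fitting a quadratic to the
signed orthogonal residuals along the line: a dish opening
anterior-superiorly beyond a 0.5 mm dead band is *type 1* (concave
anteriorly), the opposite curvature is *type 2*, anything within the dead
band is *flat*. The reported `sag_depth` is the extremal deviation of the
quadratic from its chord over the fitted segment, signed positive for
type 1.

```{r example}
library(pelvinc)
gen <- generate_phantom_volume(phantom_spec(pi_true = 45))
landmarks <- apply(gen$truth$landmarks, 1, identity, simplify = FALSE)
res <- measure_pi_pipeline(gen$volume, landmarks)
res$pi          # ~45.04 degrees on the default phantom
```

## The phantom: a stated world

Every stage is testable without any external data through a parametric
pelvis phantom with analytically known PI. The phantom is a union of
simple solids in an anatomical frame (+x left, +y anterior, +z superior):

* two concentric-shell acetabular cups (inner radius 24 mm, wall 4 mm) at
  (+-85, 0, 0) — their generative sphere centers are the ground-truth
  "femoral-head" centers, so any mixture of inner- and outer-wall points
  still fits the true center;
* a 50 x 35 mm rectangular sacral-endplate shell whose sagittal section is
  flat or a circular arc with signed sag (`endplate_concavity`; positive =
  type-1 dish);
* 6 mm spherical ASIS/PT prominences whose most ventral point is exactly
  the landmark, so the ventral refinement has an exact target;
* 5 mm capsule struts that connect everything into a single 26-connected
  component.

PI is induced by rotating the endplate patch about the left-right axis:
the patch perpendicular at its midpoint is the midpoint-to-hip-axis
direction rotated by exactly `pi_true`, so the closed-form recomputation
from the truth fields reproduces `pi_true` to machine precision
(`pi_closed_form()`), for every concavity, and is exactly invariant under
rigid motion. Voxelization samples solid membership at voxel centers
(no anti-aliasing, for bit-determinism) at the source cohort's mean voxel
size 0.98 x 0.98 x 1.00 mm, with optional Gaussian HU noise under a fixed
seed (bone 700 HU, background -1000 HU).

Geometry choices that were genuinely open, decided once:

* **Endplate position.** The default endplate midpoint (0, -60, 104)
  places the midpoint-to-hip-axis line 30 degrees from vertical. The
  point filter of stage 6 is fixed at 45 degrees from superior while PI
  recovery is exercised up to 65 degrees; since endplate inclination =
  PI minus the line's inclination, this keeps the endplate at <= 35
  degrees across the tested 35-65 degree sweep, clear of the filter with
  margin for reconstruction noise. A phantom emulating a steeper sacral
  slope would need `normal_max_angle` widened — the parameter is exposed.
* **Seed placement.** The endplate seed sits on the patch's top surface
  (chord midpoint plus sag offset): for curved patches the chord midpoint
  itself lies off the surface. The truth midpoint used by the closed form
  remains the chord midpoint.
* **Default PI 45 degrees** with 24 mm cups, near the reported normal
  cohort mean (44.97 +- 8.52 degrees).

## What a green test does and does not establish

The phantom is binary-valued: bone and background HU with a sharp
interface. It has no cortical/trabecular texture, no partial-volume
gradient, no femurs and no soft tissue. Consequences worth knowing:

* 20 HU Gaussian noise cannot flip any voxel across the 200 HU threshold
  (the margins are 500 and 1200 HU), so the noisy-phantom recovery
  criterion is dominated by the clean-path error. On real CT, noise acts
  through partial-volume voxels at the bone boundary; that pathway is not
  emulated.
* Landmark prominences are ideal spheres; real ASIS ridges are broad, and
  the ventral-refinement radius (10 mm) matters more in practice.
* The cups are full spherical shells; a real acetabulum is a lunate
  surface with a notch — the inlier band plus concave-side filter is
  designed for that, but the phantom only exercises rim rejection
  incidentally (struts piercing the cavity).

Green acceptance therefore establishes the *geometric correctness and
numerical stability* of the chain, not its robustness to anatomical
variation or imaging artifacts.

## Numerical choices

* Upward-facing test on a smoothed normal field (20 neighbour-averaging
  rounds): raw per-vertex normals on a voxelized surface scatter by tens
  of degrees around the true direction; the criterion is about surface
  orientation, not staircase noise.
* The acetabular fit declares failure when fewer than 50 inliers remain,
  when the initial radius exceeds 4x the capture radius, or when the
  converged rms residual exceeds 3% of the radius — a flat or junk
  neighbourhood then errors instead of returning a plausible-looking
  sphere.
* The line fit rejects clouds whose principal-axis sd ratio is below 1.5
  (no line-like structure); `fit_endplate_line()` needs >= 10 points.
* All pipeline randomness is absent by construction: ICP subsampling uses
  a deterministic stride, ties break by vertex index, and phantom noise is
  generated under the spec's own seed (restoring the caller's RNG state).
  Identical input and configuration give bit-identical result JSON.

## Reliability statistics

Interobserver reliability uses the two-way random-effects,
absolute-agreement, single-measurement ICC(2,1) =
(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE)/n); intraobserver uses the
two-way mixed-effects, consistency ICC(3,1) = (MSR - MSE) /
(MSR + (k-1) MSE), per rater over sessions (Shrout-Fleiss conventions;
the source method names only "two-way ANOVA" and "two-way mixed-effects
ANOVA", so the exact forms are pinned here and documented). Confidence
intervals are the F-based McGraw-Wong forms. With several raters the
per-rater ICC(3,1) values are reported individually plus their unweighted
mean and range — published summaries of this kind are ambiguous between a
confidence interval and a per-rater spread, so both are given. When a
table carries multiple sessions, the interobserver ICC averages each
rater's sessions first.

`cohort_compare()` mirrors the usual cohort battery: per-group
Kolmogorov-Smirnov normality check (against a normal with the sample
moments — a pragmatic approximation, as the classical KS test assumes
fully specified parameters), mean-centered Levene variance-homogeneity
test, then a pooled- or separate-variance t test accordingly, plus a
Pearson correlation against a covariate such as age. One caveat measured
during development: with group standard deviations of 8.00 vs 8.78 at
n = 135/185 (the published cohort moments), Levene at alpha = 0.05 has
only ~26% power, so simulations from those moments select the pooled test
in roughly three out of four replicates, not almost always.

## Known limitations

* Only the anatomical parameter PI is computed; positional parameters
  (sacral slope, pelvic tilt) are out of scope for supine CT.
* DICOM reading is restricted to explicit-VR little-endian single-frame
  CT series with rescale tags; NIfTI/NRRD cover research use.
* The MSP assumes an approximately symmetric pelvis; gross asymmetry
  (fracture, hemipelvectomy) degrades the ICP symmetry estimate, though
  the bounded-sensitivity test shows small perturbations move the plane
  by less than their own magnitude.
* The endplate point window (5000-8000) is calibrated to ~1 mm voxels;
  coarser grids need `n_min`/`n_max` adjusted (the CLI accepts a config
  JSON for this).
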
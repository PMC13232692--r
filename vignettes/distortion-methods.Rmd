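---
title: "Measuring EPI distortion of the prostate: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring EPI distortion of the prostate: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwidistort)
```

## The measurement model

Echo-planar DWI is displaced along the phase-encode (anterior–posterior)
axis in proportion to local off-resonance, which is largest where rectal
air abuts the posterior prostate.  Given a gland outline drawn on the ADC
map and a reference outline drawn on geometrically faithful DCE images of
the same anatomy, distortion is measured as a radial residual field in
polar coordinates:

1. Both contour sets are rasterized to volume masks on the acquisition
   grid, and the ADC masks are co-registered to the reference.
2. On each slice present in both sets, the **reference contour's area
   centroid** is the shared polar origin.  Both outlines are sampled at 1°
   increments; the radius at angle θ is the distance to the *farthest*
   boundary intersection along that ray, which makes the sampling robust to
   minor non-star-shapedness (prostate slices are near-convex; rays that
   cross the boundary more than twice are counted and can be inspected).
3. The signed residual is Δr(θ) = r_ADC(θ) − r_ref(θ) in mm.
4. `rms_whole` is the RMS of all (slice, angle) samples; `rms_posterior`
   restricts to θ ∈ [1°, 180°], the posterior half-plane (0° = patient
   left, 90° = posterior, counterclockwise in the axial plane).  The two
   halves partition the 360 angles exactly.

**Why the reference centroid for both profiles?**  If each contour used its
own centroid, a bulk posterior displacement of the ADC outline — exactly
the deformation susceptibility produces — would be invisible, because the
origin would travel with it.  Using the reference origin keeps such shifts
in the residual field; bulk *pose* differences are removed beforehand by
registration, which is the proper place for them.

**Registration defaults.**  Translation-only centre-of-mass alignment is
the default.  EPI susceptibility distortion is locally a
translation/stretch along phase-encode; a rigid rotation fitted to the
masks can absorb genuine distortion into pose, so rotation (by in-plane
principal-axis alignment, with the 180° ambiguity resolved by supersampled
Dice overlap) sits behind `mode = "rigid"` for sensitivity analysis.
Registration is estimated from binary masks only, and the resulting
transform is applied to contours in continuous mm space — masks are never
resampled, so the metric carries no interpolation noise.  With this design
the measured RMS is invariant (to well below 0.1 mm) under any bulk
translation of the ADC set.

**Pooling convention.**  `rms_whole` pools all (slice, angle) samples with
equal weight.  The alternative reading — RMS of per-slice RMS values — is
available as `pooling = "slice_rms"`; the two coincide whenever every
paired slice contributes a full angle grid, and differ only when slices
have missing samples.

**Numerical details.**  Voxel indices are 0-based and physical coordinates
are voxel-centre based; contours live in physical mm within each axial
slice.  Rasterization uses the even-odd rule on voxel centres with
boundary points counted inside.  Ray–edge intersection uses a half-open
edge parameter with a 1e-9 tolerance so rays through a shared vertex
register on at least one adjacent edge (duplicates are harmless because the
farthest hit is kept).  Slice reassignment after a z-translation rounds to
the nearest slice with half-slice ties kept on the lower slice.
Degenerate inputs (empty masks, zero-area polygons, empty slice pairings)
raise classed errors rather than propagating NaN.

## Rectal air and proximity volume

Air is dark on contrast-enhanced T1 imaging, so segmentation is a simple
threshold *restricted to the rectum outline*, with face-connected
components below 5 voxels discarded as noise.  The scanner-specific
threshold is a free parameter; the default is the 2.5th percentile of
within-body intensities, and phantoms carry an explicit threshold midway
between their tissue and air signal levels.

The proximal volume is computed with an exact anisotropic Euclidean
distance transform (Felzenszwalb–Huttenlocher lower-envelope algorithm,
compiled): air voxels whose distance to the nearest prostate voxel is at
most 20 mm — equivalently the intersection of the air mask with the
prostate dilated by 20 mm — counted and scaled by the voxel volume.
Distance is measured to the prostate *surface*, not its centroid, because
proximity to the recto-prostatic interface is what drives the artefact.
The implementation is checked voxel-exactly against an all-pairs
brute-force oracle on randomized grids, and proximal volume is monotone in
the distance parameter by construction.

## Cohort statistics

- **Descriptives** are median and IQR with linear-interpolation quantiles
  (R type 7).
- **Paired comparisons** use the Wilcoxon signed-rank test, two-sided,
  dropping zero differences (Wilcoxon's original convention; the choice is
  documented because conventions differ).  The null distribution is exact
  up to 25 non-zero pairs — by the signed-rank distribution without ties
  and full 2^n sign enumeration with mid-ranks for tied small samples —
  and a tie-corrected, continuity-corrected normal approximation beyond.
  Two-sidedness is defined symmetrically as P(|W − E W| ≥ |w − E W|), so
  the exact paths agree with enumeration identically.
- **Fisher's exact test** on the dichotomized Likert scores (≥4 =
  appreciable air) is two-sided by minimum-likelihood summation.
- **Gwet's AC2** with quadratic weights w_kl = 1 − (k−l)²/(q−1)² uses
  chance agreement p_e = T_w/(q(q−1)) Σ_k π_k(1−π_k) with category
  propensities averaged over the two raters; interpretation bands from
  <0 (poor) to 0.81–1.00 (almost perfect) are attached to the output.
- **The air threshold** `V_thresh-air` comes from a univariate logistic
  model P(appreciable) = σ(β₀ + β₁·air) as the probability-0.5 volume
  −β₀/β₁.  The paper-style "optimal dichotomizing threshold" is not a
  uniquely defined rule; for a univariate monotone model the usual
  candidates (Youden's J on fitted probabilities, maximum accuracy under
  equal priors) coincide at the 0.5 crossover, which is why that
  operationalization was chosen.  Perfect separation is reported as the
  midpoint between the class-extreme volumes with a flag instead of
  divergent coefficients, and a non-positive slope is refused rather than
  reported as a meaningless negative threshold.
- **Subgroup analysis** (`subgroup_compare`) repeats the paired
  comparisons inside the subgroup with supine air above the threshold and
  emits the long-format air-versus-distortion scatter table; subgroups
  smaller than 5 are reported as not evaluable.

No multiplicity correction is applied across tests, matching the analysis
design this package accompanies.

## What the synthetic generator emulates

`make_phantom()` builds an ellipsoidal prostate (default semi-axes
20 × 17 × 22 mm ≈ 31 cm³, a typical gland) with a smooth low-order surface
perturbation, on a 24 × 96 × 96 grid at 3 × 1 × 1 mm — representative of
axial prostate MRI.  A rectum tube (radius 14 mm) sits posterior to the
gland, and an air pocket of controllable volume grows inside it from the
anterior rectal wall, hitting the target volume to within one voxel.  The
intensity volume gives tissue ~100 and air ~5 signal units with Gaussian
noise.  Identical seeds give bitwise-identical phantoms.

`distort_contours()` applies a smooth angular bump
A·exp(−(θ−90°)²/2σ²) per slice — along +y (`posterior_bump`, the
susceptibility-like default), radially (`radial_bump`), or uniformly
(`dilate`) — to the contour vertices in continuous space.  Because the
deformation acts on contours, not on rasterized masks, its expected RMS is
computable: `expected_distortion()` densely resamples the boundary,
applies the same displacement, and interpolates the polar profile onto the
1° grid.  That predictor shares no code with the ray-casting metric, and
the two agree within 2% across bump amplitudes of 1–5 mm (rasterization
effects are tested separately in the IO layer).  Known-deformation
recovery is evaluated with the identity transform, since the predictor
models the raw deformation; registration behaviour is tested separately.

`make_cohort()` draws per-patient scalar measurements directly from the
statistical structure the analysis assumes:

| parameter | default | meaning |
|---|---|---|
| `air_meanlog`, `air_sdlog` | 0.67, 1.30 | supine proximal air ~ log-normal, median ≈ 2 cm³, ~1/3 of patients above 4 cm³ |
| `reduction_shape1/2` | 2, 3 | prone air = supine × Beta(2,3) factor (median ≈ 0.31) |
| `baseline_mm` | 3.0 | posterior distortion floor below the knee |
| `prone_baseline_factor` | 1.06 | mild prone penalty at low air (prone medians slightly exceed supine in the whole cohort) |
| `slope_mm_per_cm3` | 0.40 | distortion response above the knee |
| `knee_cm3` | 4 | air volume where the response starts |
| `noise_cv` | 0.18 | log-scale SD of multiplicative measurement noise |
| `likert_cutpoints` | 0.5, 1.8, 4.0, 7.0 | latent-air cutpoints of the 5-point scale; the ≥4 crossover sits at the knee |
| `rater_disagree` | 0.15 | probability the second rater differs by one category |

The air→distortion link is piecewise-linear with a knee — the minimal
model consistent with a scatter in which distortion is flat below ~4 cm³
and grows with air above it.  The Likert link is logistic in air volume
with its probability-0.5 crossover at the knee, so the logistic threshold
estimator is well-specified under the generator and should recover
≈ 4 cm³.  These defaults were fixed once, by calibration against the
published clinical pattern the generator emulates (whole-cohort posterior
distortion medians near 3 mm with no significant position effect; a
high-air subgroup of roughly 19/52 patients in which prone imaging reduces
distortion from ≈ 4.6 to ≈ 3.5 mm), before the test suite was written, and
are not tuned thereafter.

**What passing tests do and do not show.**  The phantoms are smooth,
near-convex, noise-free geometries with a single air pocket; they validate
the geometry, the transforms, and the statistics pipeline end to end.
They do not exercise segmentation variability, multi-pocket air
distributions, through-plane distortion components, motion, or the
correlation structure of real raters, so agreement on phantoms bounds
implementation error, not clinical measurement error.

## Problem sizes

The test suite and acceptance script use one 24 × 96 × 96 phantom per
scenario, 50 randomized grids up to 64³ for the distance-transform oracle,
100 random polygons for the ray oracle, 100 random tables for the
signed-rank enumeration oracle, and 50 synthetic cohorts of n = 200 (plus
20 of n = 52) for threshold recovery and the subgroup pattern — sizes at
which every oracle is exhaustive or near-exhaustive while the whole suite
runs in well under a minute per module.

## Known limitations

- Slice pairing is by index after the z-component of the transform; there
  is no through-plane resampling of contours.
- The farthest-intersection rule makes strongly non-star-shaped outlines
  measurable but not necessarily meaningful; the crossing-count flag
  should be consulted for such data.
- Gwet's AC2 is implemented for exactly two raters.
- The intensity model knows nothing about coil shading or partial volume;
  the air threshold is a free parameter on real data.
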
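# dwidistort

Quantifies geometric distortion of prostate diffusion-weighted MRI (DWI)
from paired segmentations, and relates it to rectal air across a cohort.

## The problem

Echo-planar DWI — the sequence behind ADC maps used for prostate cancer
detection — is geometrically warped near air–tissue interfaces.  Rectal air
sitting against the posterior prostate perturbs the B0 field and displaces
the imaged gland along the phase-encode (anterior–posterior) direction,
which can distort or silence exactly the region where most tumours arise.
Dynamic contrast-enhanced (DCE) imaging of the same anatomy is
geometrically faithful, so the *difference* between a gland outline drawn
on the ADC map and one drawn on DCE is a direct measurement of distortion.

This package implements that measurement and the surrounding cohort
analysis for anyone studying patient positioning (supine vs prone), bowel
preparation, or acquisition strategies against EPI distortion:

1. **Masks from outlines** — per-slice closed contours (mm coordinates) are
   rasterized to label volumes; NIfTI-1 and a simple CSV contour dialect are
   the interchange formats.
2. **Co-registration** — the ADC mask is aligned to the reference mask by
   centre-of-mass translation (optionally rigid in-plane rotation), so bulk
   pose differences do not masquerade as distortion.
3. **Polar residuals** — on each paired slice both outlines are sampled at
   1° increments about the reference contour centroid; the signed radial
   residual is Δr(θ) = r_ADC(θ) − r_ref(θ) in mm.
4. **RMS reduction** — residuals pool into a whole-gland RMS and a
   posterior-half RMS (θ ∈ [1°, 180°], +y = posterior), the
   `Distortion_post` statistic in mm.
5. **Rectal air** — air is segmented inside the rectum outline by intensity
   threshold; an anisotropic Euclidean distance transform gives the air
   volume within 20 mm of the prostate (`Rectal Air_prox`, cm³).
6. **Cohort statistics** — median/IQR descriptives, paired Wilcoxon
   signed-rank tests, Fisher exact test on dichotomized 5-point rectal-air
   Likert scores (≥4 = appreciable air), Gwet's AC2 agreement with
   quadratic weights (Gwet, *Br J Math Stat Psychol* 2008), and a logistic
   regression threshold `V_thresh-air` = −β₀/β₁, the air volume at which
   appreciable air reaches probability 0.5.

A synthetic module generates paired supine/prone phantoms (prostate,
rectum, air pocket, intensity volume) and whole cohorts with known ground
truth, so every stage is testable without patient data.

## Worked example

```r
library(dwidistort)

# a phantom with 6 cm^3 of rectal air, and a 4 mm posterior-bump
# deformation standing in for susceptibility distortion
ph  <- make_phantom(phantom_spec(seed = 7, air_cm3 = 6))
adc <- distort_contours(ph$contours,
                        deformation_spec(4, mode = "posterior_bump",
                                         width_deg = 30))

measure_distortion(ph$contours, adc, registration = "translation")
#> <distortion_result> rms_whole = 1.158 mm, rms_posterior = 1.338 mm
#>   (14 slice(s) used, 0 dropped, pooled)

air <- segment_air(ph$intensity, ph$rectum, threshold = ph$air_threshold)
air_proximity_volume(air, ph$prostate, distance_mm = 20)
#> <air_measure> total 6.000 cm^3, 5.418 cm^3 within 20 mm of prostate (1 pocket(s))
```

The posterior RMS exceeds the whole-gland RMS because the deformation is
concentrated at the recto-prostatic interface; the values are lower than
the raw 4 mm bump because the RMS averages over angles and slices and
centre-of-mass registration absorbs the bump's bulk displacement.

Cohort level, on a synthetic 52-patient cohort:

```r
co <- make_cohort(cohort_spec(n = 52, seed = 7))
subgroup_compare(co$cohort, v_thresh = 4)
#> <cohort_summary> n = 52, subgroup (supine air > 4 cm^3): n = 19
#> whole cohort:
#>   distortion  supine 3.49 (2.88-3.89) vs prone 3.40 (3.06-3.91) mm, p = 0.139
#>   air         supine 2.24 (1.14-5.35) vs prone 0.76 (0.34-2.07) cm^3, p = 3.61e-10
#> subgroup:
#>   distortion  supine 4.63 (3.73-9.35) vs prone 3.39 (2.94-5.24) mm, p = 0.000336
#>   air         supine 7.15 (5.18-17.15) vs prone 2.29 (1.76-10.07) cm^3, p = 3.81e-06
```

This reproduces the clinical pattern the pipeline is designed to detect:
prone positioning reduces proximal rectal air everywhere, but reduces
posterior distortion significantly only in the high-air subgroup.

A thin command-line front end over the same functions lives at
`inst/scripts/dwidistort-cli.R` (subcommands `distortion`, `air`, `cohort`,
`synth`).

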
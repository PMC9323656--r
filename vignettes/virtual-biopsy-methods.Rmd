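---
title: "Virtual-biopsy radiomics: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual-biopsy radiomics: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Early-stage (stage I) non-small cell lung cancer has a broadly favorable
prognosis, yet a substantial minority of patients with apparently identical
tumor characteristics die within two years of diagnosis. One biological
explanation is the inflammatory state of the tumor microenvironment: a
macrophage-rich, inflammasome-active peritumoral zone (high CD68 and IL-1β
staining) correlates with poor outcome. Inflammatory infiltrate increases
tissue cellularity, and denser tissue attenuates X-rays more, so the
peritumoral zone of a poor-prognosis patient should look different on a
routine CT scan — if one measures it in the right place.

The "virtual biopsy" does exactly that: instead of extracting radiomic
features from the whole segmented lesion (whose volume varies hugely between
patients), a sphere of fixed 1-cm diameter is centred on the lesion contour so
that it straddles tumor and peritumoral tissue in a standardized way. Two such
spheres are placed per lesion — one anchored in the axial plane through the
lesion centroid, one in the coronal plane — and a third control sphere is
placed in muscle on the same axial slice. Muscle carries no outcome
information, so any feature that separates the outcome groups in the muscle
sphere is measuring scanner or reconstruction noise, not biology, and is
discarded. The whole placement is repeated by a second observer, and only
features significant in both observers' data sets survive.

## Pipeline overview

1. **Geometry** (`place_biopsy_spheres`, `place_control_sphere`,
   `voxelize_sphere`): spheres are world-coordinate objects in millimetres; a
   voxel belongs to a sphere when its centre lies within `diameter/2`
   (anisotropic spacing respected). The boundary is the 6-connectivity surface
   of the lesion mask.
2. **Features** (`extract_feature_vector`): intensity-based energy
   (`sum(x^2)`), maximum, median, and 90th intensity percentile on raw HU;
   GLCM autocorrelation averaged over the 13 unique 3D directions and GLRLM
   gray-level non-uniformity averaged over the 4 in-plane directions and all
   axial slices, both on gray levels discretized with a fixed 25-HU bin width
   from −1000 HU.
3. **Selection** (`select_features`): per observer, per feature, an exact
   two-sided Mann–Whitney test between outcome groups; the muscle-sphere
   noise filter; intersection of the two observers' significant sets at
   `alpha = 0.05` (the boundary value counts); ROC with Youden-index cutoffs
   for the selected features.
4. **Outcome** (`survival_ihc_analysis`): Kaplan–Meier curves (via the
   survival package), a two-group log-rank test, and the semiquantitative IHC
   staining score (percentage category 0–4 times intensity 0–3, range 0–12)
   compared between groups with a pooled-variance t-test.

## Statistical choices

**Exact Mann–Whitney.** With 8 + 7 patients there are only `choose(15, 8) =
6435` group assignments, so the permutation null of the U statistic is
enumerated exactly over the observed pooled values (midranks, so ties are
handled by construction); the two-sided p doubles the smaller tail. The
normal approximation with tie and continuity correction is used only beyond
pooled size 16. Exactness matters here: asymptotic p-values are unreliable at
these sample sizes and the selection rule sits right at `p = 0.05`.

**One tumor value per patient.** Each observer contributes two biopsy spheres
per patient (axial, coronal). The group test needs one value per patient, so
the default reduces the two spheres by their mean (`combine_vois = "mean"`);
either single sphere can be chosen instead. This keeps the test's sampling
unit the patient, not the sphere, and preserves the 8-vs-7 exact enumeration.

**No multiplicity correction by default.** The dual-observer intersection is
the procedure's robustness device; a Benjamini–Hochberg option exists
(`adjust = "BH"`) but is off by default to mirror the original procedure.

**Muscle filter reading.** "A feature that differs between the muscle
spheres" admits two readings: muscle values differing between *outcome
groups* (the default, applied within each observer set, excluding on
significance in either), or differing between the *two observers'* muscle
spheres pooled across patients (`mode = "between-observers"`). The
group-comparison default matches how the control result is reported alongside
the tumor-sphere result; the report records which mode was used. Note the
filter is intrinsically noisy: under the null it excludes each feature with
probability ≈ 4% (the exact-test mass below 0.05 at these group sizes), which
bounds how often any true feature can survive repeated cohorts.

**ROC orientation and cutoffs.** AUC comes from the rank formula (identical
to `U/(n1*n2)`, ties counted half). Both orientations are considered and the
one with AUC ≥ 0.5 is reported, since a cutoff's direction is otherwise
ambiguous. The Youden cutoff maximizes sensitivity + specificity − 1 over all
distinct observed values; ties break toward higher sensitivity, then lower
cutoff.

**IHC percentage bins.** The five-level scheme is ≤ 5% → 0, 6–25 → 1,
26–50 → 2, 51–75 → 3, > 75 → 4. Fractional percentages are rounded half-up
to an integer first, which resolves readings such as 5.4% (→ 0) and 25.5%
(→ 2) the way the integer-valued scheme implies.

**Survival quartiles.** The q-th quartile survival time is the earliest time
at which the Kaplan–Meier curve drops to 1 − q or below; "third-quartile
survival" is thus the time by which 25% of patients have died, which is the
reading consistent with a 24-month third quartile alongside a five-year OS
near 60%.

## Numerical and geometric conventions

* Internal axis order is (z, y, x) with spacing in mm; world coordinates are
  axis-aligned, a voxel is a point sample at its centre, and all membership
  tests use voxel centres. NIfTI input with a different stored orientation is
  reoriented on load.
* The sphere anchor on the lesion contour is chosen deterministically: among
  the boundary voxels in the centroid's axial (resp. coronal) plane, the one
  nearest the centroid of that plane's boundary points, with ties broken by
  lowest (z, y, x) index. A user-supplied anchor overrides this, since a
  radiologist may anchor anywhere on the contour.
* Discretization uses a fixed bin size (25 HU from −1000 HU, configurable),
  the recommended scheme for CT; features are computed on the native grid (no
  resampling), which keeps the texture oracles exact. The vendor settings
  behind the original measurements are unpublished, so numeric equality with
  the original feature values is not a meaningful target.
* Texture features are reported on bin indices. Autocorrelation in raw HU²
  would be ill-defined for negative HU, so the "HU" suffix in vendor feature
  names is treated as a label.
* GLCM/GLRLM matrices with no pairs/runs are excluded from the directional
  average rather than contributing zero, which avoids diluting thin samples.
* The 90th intensity percentile is the lowest sample value strictly greater
  than at least ⌈0.9 N⌉ sample values, falling back to the maximum for
  constant samples. This discrete definition is exactly testable by
  enumeration.
* DICOM support is a minimal reader for uncompressed explicit-VR
  little-endian axial CT series (rescale slope/intercept applied, slices
  sorted along the stack normal, > 1% spacing variation rejected), plus a
  matching synthetic series writer. It is not a general DICOM implementation.

## The synthetic cohort generator

No patient images are distributed, so the generator builds desk-scale
phantoms with the statistical structure the pipeline is designed to detect:

* **Grid**: 96³ voxels at 1 mm isotropic — small enough that a full 15-patient
  cohort (90 sphere extractions) runs in a couple of seconds, large enough
  that lesion, rim and muscle are well separated.
* **Lesion**: an ellipsoid of soft-tissue density (30 ± 30 HU) with
  per-patient semi-axes drawn uniformly from 8–11 mm, in a lung background of
  −800 ± 50 HU.
* **Peritumoral rim**: a 7-mm shell around the lesion. The long-survival
  group gets a mild ground-glass halo (−420 ± 30 HU) with spatially smooth
  texture (two passes of a 3³ box filter over the noise field, rescaled to
  unit marginal variance, so gray-level runs are long and concentrated). The
  short-survival group gets the same shell shifted by +500 HU — consolidated,
  denser-than-tumor tissue — with 70% of rim voxels re-drawn independently,
  fragmenting the runs. The density offset drives the four intensity features
  and GLCM autocorrelation; the fragmentation drives GLRLM gray-level
  non-uniformity. The rim is deliberately thicker than the sphere radius so
  the 1-cm sphere samples only tumor and peritumoral tissue; thinner rims let
  variable amounts of lung into the sphere, and that geometric variance — not
  any group difference — then dominates the energy feature.
* **Muscle**: a homogeneous slab (50 ± 15 HU voxel noise) near the grid edge
  with identical distribution in both groups. Two realism details matter
  statistically. The noise field gets one smoothing pass, emulating the
  spatial correlation a reconstruction kernel leaves in uniform tissue. And
  each patient's slab carries a constant density offset (SD 8 HU), modelling
  the well-documented inter-patient variability of muscle attenuation
  (myosteatosis); as on real CT, that offset — not within-sphere sampling
  noise — dominates the between-patient spread of muscle-sphere statistics,
  so the two observers' nearly-coincident control spheres rank patients
  almost identically and the muscle filter behaves like a single test per
  feature rather than two independent ones.
* **Observers**: the second observer's spheres are the first observer's
  displaced by at most one voxel per axis (uniform, seeded).
* **Outcome**: the short group draws event times uniformly from 6–24 months
  (all deaths); the long group is censored alive at 61–72 months. IHC scores
  are drawn high (≥ 55% positivity, moderate/strong intensity) for the short
  group and low for the long group, for both CD68 and IL-1β.
* **Determinism**: every draw derives from the master seed and the patient
  index, so cohorts are bit-reproducible.

What the generator does *not* emulate: anatomy (airways, vessels, chest wall
curvature), scanner and kernel differences, partial-volume effects, lesion
spiculation, or segmentation error beyond the 1-voxel observer jitter.
Passing the recovery suites therefore shows that the pipeline detects a
planted peritumoral density/texture contrast through the full
geometry-extraction-selection chain — not that it would detect the subtler
contrasts of real cohorts.

## Simulation study sizes

The recovery properties are checked over 100 independently seeded cohorts
with the rim effect on (each of the four intensity features and GLCM
autocorrelation must be selected in at least 95 of them, with both observers'
AUCs at least 0.9 whenever selected) and 100 cohorts with the rim effect off
(mean selected-feature count at most 5% of the candidates). The muscle-filter
null rate is checked against binomial bounds over 200 simulated features.
Smaller per-module suites use reduced grids (64³) for speed; the 100-run
suites always use the default 96³ conditions.

## Known limitations

* The implemented feature families cover the six selected features plus a few
  intensity extras; this is not a full IBSI catalog (no GLSZM, NGTDM,
  histogram or filtered families).
* The muscle filter's ~4–5% null exclusion rate is a property of the
  specified procedure, so even a perfectly separated feature survives 100
  repeated cohorts only ~95–96 times on average.
* Lesion masks are inputs; the semi-automated segmentation that produced the
  original contours is out of scope.
* The DICOM path reads one uncompressed explicit-VR little-endian series per
  directory; compressed transfer syntaxes and oblique orientations are
  rejected rather than resampled.
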
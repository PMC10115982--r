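---
title: "Evaluating candidate structure sets against a gold standard"
author: "segeval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating candidate structure sets against a gold standard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segeval)
```

## The evaluation problem

Head-and-neck radiotherapy planning requires segmenting up to 42
organs-at-risk (OARs) on the planning CT. When a new contour source — an
autosegmentation model, revised or unrevised, or a human workflow — is
validated, its structure sets are compared against gold-standard (GS) expert
contours on three axes: geometric agreement, impact on plan dose statistics,
and contouring time. `segeval` implements that comparison pipeline and a
synthetic phantom generator that produces cohorts with analytically known
answers, so every stage can be verified without patient data.

All geometry lives on world-aligned anisotropic voxel grids (mm; the default
phantom uses the typical planning-CT voxel of 1.27 × 1.27 × 2 mm). Oblique
acquisitions are out of scope, and CT intensities are never used: every
metric depends only on binary occupancy and, for dosimetry, a dose field.

## Geometric metrics and their conventions

The package computes volumetric Dice (VDSC), surface Dice SDSC(τ) at
τ ∈ {1, 1.5, 2, 3} mm, the 95th-percentile Hausdorff distance (HD95), added
path length APL(t) at t ∈ {1, 2, 3, 5} mm, contour Dice CDC(t) at 1 mm,
voxel precision/sensitivity/specificity, and signed volume and centroid
shifts. Several conventions are deliberately pinned down because the
literature leaves them open:

- **Surface representation.** SDSC is area-weighted over *boundary faces*
  (faces between foreground and background voxels, or the grid edge), each
  carrying its centroid (mm) and area (mm²); HD95 and CDC use *boundary
  voxel centers*; APL uses the reference's *slice-wise in-plane boundary
  pixels*, with full 3D distances to the candidate's slice-wise boundary
  pixel set, converted to mm by the mean in-plane pitch. One boundary
  extractor feeds all three representations.
- **Distances.** Every nearest-surface distance comes from an exact
  separable Euclidean distance transform that honors anisotropic spacing.
  For face centroids the transform runs on a half-step lattice on which
  every face centroid is an exact lattice site, so the distance-transform
  values equal brute-force all-pairs distances to machine precision (the
  test suite asserts agreement within 1e-9 on hundreds of random mask
  pairs).
- **HD95 pooling.** The directed 95th percentiles (linear interpolation
  between order statistics, R's type-7 quantile) are combined by `max`, the
  common convention.
- **CDC variant.** CDC is defined here as the Dice overlap of boundary
  bands: |S_A ∩ B_t(S_B)| + |S_B ∩ B_t(S_A)| over |S_A| + |S_B| in voxel
  counts.
- **Specificity** depends on the grid extent through the true-negative
  count; it is computed over the shared reference grid and should be read as
  extent-dependent.
- **Empty inputs.** Metrics on empty masks raise classed errors rather than
  returning conventional values, because the study design excludes
  structures not present in all arms before any comparison. A structure
  *delivered but empty* counts as absent for presence accounting but as an
  error for geometry.
- **Rasterization.** Planar contours become masks by the even-odd
  voxel-center rule with a deterministic half-open tie convention; vendor
  behavior at polygon boundaries varies, so this explicit rule is the
  package's convention.
- **Grid reconciliation.** Metrics require a shared grid; a candidate on a
  different grid is resampled to the reference (GS) frame by nearest
  neighbor (per-axis nearest, ties toward the lower index), with a warning.

## Dosimetry

The dose field is taken as given (plan optimization is out of scope). PTVs
are built from CTVs by isotropic Euclidean expansion in mm (default 3 mm)
cropped to the body surface. Each OAR is evaluated on its region outside the
union of PTVs; if less than 0.1 cc remains, the structure is excluded from
dosimetric analysis. DVHs are exact voxel-sample curves — every foreground
voxel contributes its volume at its dose — with no histogram binning.
D0.03cc interpolates linearly on the sorted voxel-dose profile at the
0.03 cc boundary, which removes any bin-width free parameter. When dose and
structure grids differ, dose is interpolated trilinearly to structure voxel
centers (dose is a smooth field; nearest-neighbor sampling would alias the
DVH tails).

Plan quality is scored by a template of DVH objectives (structure,
statistic, direction, threshold, points, optional linear partial-credit
ramp). The normalized plan quality metric (NPQM) is 100 × achieved/maximum,
with the maximum taken over objectives whose structures are present and not
excluded — that normalization is what makes cases with different rosters
comparable, and it is why an absent structure drops out of numerator and
denominator together. Binary scoring is the default and ramped scoring is
available; the shipped head-and-neck template (serial organs capped on
D0.03cc, parallel organs on Dmean, targets on mean dose at 98% of
prescription) is explicitly illustrative, not an institutional protocol.

## Study statistics

Group comparisons use two-sided paired t-tests at α = 0.05 with no
multiple-testing correction (the report records how many tests it ran);
means are reported with t-based 95% CIs. Pooled comparisons pair at the
case × structure level; per-OAR comparisons pair at the case level — the
pairing unit is a genuine design choice and is recorded in the report
structure. Degenerate difference vectors are reported descriptively:
all-zero differences give p = 1 flagged `no-difference`; zero-variance
nonzero differences are flagged `degenerate-variance` rather than given a
fabricated p-value.

Time savings is the per-case relative reduction in total contouring time,
summarized by mean and 95% CI, with a one-sided test against a 30%
clinical-significance margin at α = 0.025; the corresponding a-priori power
uses the noncentral t distribution. The per-case-ratio definition (rather
than ratio of means) is chosen so that the CI is a CI on savings itself.
Missing-structure behavior is summarized by a presence contingency table
over cases × expected structures, with sensitivity/specificity reported to
the nearest integer percent.

## The synthetic cohort: what it emulates, and what it does not

The generator mirrors the shape of a contouring validation trial: 19
analyzable cases by default, a 42-structure OAR roster laid out as geometric
primitives in a head-shaped phantom (schematic positions and sizes, not an
atlas), 1–3 spherical targets with prescriptions in the 54–72 Gy range, a
small rate of genuinely missing structures (default 2.6% per structure, the
order of magnitude implied by presence counts in such trials), and three
candidate arms whose perturbation severity is ordered: the unrevised model
arm closest to GS, the revised model arm close, the manual arm farthest.

Perturbations are drawn per structure and case: an isotropic normal
translation, a fixed dilation/erosion, a smooth correlated boundary
displacement, optional slice dropout, and absence sampling (miss and
false-presence probabilities). Two implementation choices matter:

- **Continuum signed-distance perturbation.** Generated structures are
  perturbed in the continuum: the primitive's signed distance field is
  translated, shifted by the dilation radius, and displaced by the noise
  field *before* rasterization. Lattice morphology (dilating the voxel set
  of a rasterized sphere) systematically underestimates the continuum
  dilation by a fraction of a voxel per surface; operating on the signed
  distance leaves only pure voxelization error, so a dilation by r of a
  sphere of radius R recovers the 4/3π((R+r)³−R³) shell within 3% and a
  voxel-multiple translation is recovered exactly by the centroid shift.
  The signed distance is exact for spheres, boxes, tubes and rings, and a
  standard first-order approximation for ellipsoids. A raster-level
  `perturb_mask()` remains for arbitrary masks, with lattice semantics.
- **Boundary noise as a band-limited field.** The displacement is a smooth
  Gaussian random field (i.i.d. values on a coarse lattice at the
  correlation length, default 20 mm, trilinearly interpolated) applied to
  the signed distance, not i.i.d. voxel flips — so surface metrics degrade
  gracefully and monotonically with the amplitude.

Timing: standard-arm initial and revision durations are lognormal with
means 2.3 h and 1.1 h (shape parameters 0.2 and 0.5, chosen to reproduce
plausible case-to-case spread); the experimental arm scales the standard
total by 1 − s/100 with per-case savings s from a normal distribution
truncated above at 99% (durations must stay positive), SD 24% (the spread a
65–88% CI at n = 19 implies), and location solved so the *true* mean
savings equals the configured 76% exactly. The truncation skews the savings
distribution slightly left, which costs the t-based CI a little coverage;
the calibration suite measures coverage at n = 19 over 1000 replicates and
requires at least 93%.

What the phantom does **not** emulate: real anatomical shape complexity and
inter-structure spatial correlation, observer-specific systematic bias,
realistic dose gradients from optimized plans, and image-driven errors.
Passing the synthetic suite certifies the *measurement pipeline* — that the
metrics, DVH statistics and study tests compute what they claim on known
inputs — not that any particular contour source is clinically acceptable.

## Problem sizes and numerical tolerances

The validation suites run on deliberately compact problems: oracle
equivalence on ≥ 200 random mask pairs within 20³ grids (tolerance 1e-9 mm;
counts exact), analytic sphere recoveries on 1 mm grids (lens-overlap Dice
within 0.01, dilation shell within 3%), dosimetry checks with exact
conservation, and cohorts of 19 cases with 5–8 structures on 32³-scale
grids for calibration and arm-ordering recovery. The analysis drivers use a
10-case, 8-structure cohort by default; the full 42-OAR phantom
(`hn_oar_roster()`) plugs into the same functions unchanged. Absence of a
DICOM reader in the R dependency stack means structure sets enter via NIfTI
masks, JSON manifests, or in-memory objects; planar contours can be supplied
programmatically and rasterized with `rasterize_contours()`.

## Known limitations

- Axis-aligned grids only; no oblique or tilted geometries.
- The ellipsoid signed distance is first-order approximate away from the
  axes (exact on them); its residual error is far below the perturbation
  scales used anywhere in the package.
- Specificity and any TN-derived rate depend on the grid extent.
- NPQM comparisons are only as meaningful as the scoring template; the
  shipped template is illustrative.
- The raster-level `perturb_mask()` dilation carries the usual half-voxel
  lattice bias; use `perturb_primitive()` (the generator's path) when
  analytic recovery matters.
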
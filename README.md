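# segeval

Geometric and dosimetric evaluation of radiotherapy structure sets.

When a new source of organ-at-risk (OAR) contours — an autosegmentation
model, a trainee, another institution — is validated for head-and-neck
radiotherapy planning, its contours are compared against gold-standard (GS)
expert contours along three axes: geometric agreement, dosimetric impact on
the treatment plan, and workflow time savings. `segeval` implements that
entire evaluation pipeline for R, for medical physicists and clinical
researchers running contouring validation studies, together with a synthetic
phantom cohort generator with analytically known answers so the pipeline can
be verified end to end without patient data.

## What it computes

For a candidate mask $A$ and reference mask $B$ on a shared (anisotropic)
voxel grid:

- **Volumetric Dice** $\mathrm{VDSC} = 2|A \cap B| / (|A| + |B|)$ over
  foreground voxels.
- **Surface Dice** $\mathrm{SDSC}(\tau)$: the area-weighted fraction of the
  two boundaries lying within distance $\tau$ of each other, computed from
  boundary faces (centroids in mm, areas in mm²).
- **HD95**: the larger of the two directed 95th-percentile nearest-neighbor
  distances between boundary voxel centers.
- **Added path length** $\mathrm{APL}(t)$: the length of reference contour
  farther than $t$ from the candidate surface, slice-wise in the axial
  plane — a proxy for the manual editing effort a reviewer would spend.
- **Contour Dice** $\mathrm{CDC}(t)$: Dice overlap of the two boundary bands
  at tolerance $t$.
- Voxel **precision / sensitivity / specificity**, signed **ΔVolume** (cc)
  and **ΔCentroid** (mm).

All distances use exact Euclidean distance transforms honoring anisotropic
spacing (e.g. the typical 1.27 × 1.27 × 2 mm planning-CT voxel), never
index-space approximations.

On the dosimetric side: PTV construction (uniform margin cropped to the
body), OAR evaluation regions (OAR minus PTVs, with a 0.1 cc exclusion
rule), exact voxel-sample DVH curves, Dmean / D0.03cc / VxGy statistics, and
a configurable plan-quality scoring template whose achieved/maximum ratio is
the **normalized plan quality metric** (NPQM, in % — normalization makes
cases with different structure rosters comparable).

Study statistics: structure-presence contingency tables with
sensitivity/specificity, means with 95% CIs, two-sided paired t-tests,
time-savings analysis against a clinical-significance margin (one-sided
noncentral-t power included), OAR threshold counts, and report tables in
the shapes used by contouring trials.

## Worked example

```r
library(segeval)

grid <- voxel_grid(origin = c(-20, -20, -20), spacing = c(1.27, 1.27, 2),
                   shape = c(33, 33, 21))
gs   <- primitive_mask(grid, "sphere", center = c(0, 0, 0), size = 12)
cand <- perturb_primitive(grid, "sphere", c(0, 0, 0), 12,
                          translation = c(2, 1, 0), dilation_mm = 1)

volumetric_dice(cand, gs)        # 0.832
surface_dice(cand, gs, tau = 1)  # 0.366
hausdorff95(cand, gs)            # 3.23 mm
added_path_length(cand, gs, 1)   # 455.9 mm
delta_volume(cand, gs)           # +2.08 cc
delta_centroid(cand, gs)         # 2.29 mm
```

The candidate is the same 12 mm sphere shifted 2.2 mm and uniformly expanded
1 mm: voxel overlap stays high (VDSC 0.83) while the stricter surface
metrics see most of the boundary displaced by more than 1 mm (SDSC 0.37,
APL ≈ 456 mm of contour to redraw), and the centroid shift recovers the
applied translation magnitude. This dissociation between volumetric and
surface agreement is exactly why validation studies report both.

## Analysis workflow

`analysis/` contains the numbered drivers that reproduce a full synthetic
study (each writes its tables under `results/`):

1. `01_simulate_cohort.R` — simulate a cohort: GS structure sets, three
   candidate arms with graded perturbation severity, dose fields, timing
   records.
2. `02_geometry_metrics.R` — the full geometric battery per case, structure
   and arm.
3. `03_dosimetry.R` — |ΔDmean|, |ΔD0.03cc| and |ΔNPQM| against the GS.
4. `04_study_report.R` — timing summary with the time-savings endpoint,
   pooled and per-OAR paired comparisons, dosimetric summary, presence
   contingency.

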
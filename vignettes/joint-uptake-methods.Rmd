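---
title: "Methods: joint-level SUV quantification and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint-level SUV quantification and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jointsuv)
```

## The measurement model

The package quantifies tracer uptake of large joints (knee, hip,
sacroiliac) on coregistered PET/CT. The target statistic is the **global
SUVmean**: the unweighted arithmetic mean of the body-weight standardized
uptake value over every voxel of the segmented joint region,

$$\mathrm{SUV}(v) \;=\; \frac{C(v)}{D(t)\,/\,W},$$

with \(C(v)\) the PET activity concentration in Bq/mL, \(W\) the body
weight in grams, and \(D(t)\) the injected dose in Bq decay-corrected to
acquisition time, \(D(t) = D\,2^{-\Delta t/T_{1/2}}\) with the
fluorine-18 half-life \(T_{1/2} = 109.77\) min. `activity_to_suv()`
implements exactly this; `decay_correct = FALSE` accommodates scanners
that already correct the image to injection time.

Assumptions baked into the model:

* the PET and CT are rigidly coregistered, axis-aligned, and expressed on
  world grids `world = origin + index * spacing` (mm);
* the PET volume is in Bq/mL (quantitative reconstruction);
* uptake is measured over *bone* captured by a CT attenuation rule, not
  over soft tissue.

## Pipeline stages and their parameters

Each joint and side is processed by `quantify_joint()` as five explicit
stages. Errors are tagged with the failing stage.

**1. Region of interest (`build_roi`)** — rectangular, landmark-driven,
in world mm, converted to voxel indices by the center-inside-inclusive
rule (a voxel belongs to the box when its center lies inside the mm
bounds). Per joint:

* *knee*: axial slab from 4 cm inferior to 4 cm superior of the
  intercondylar eminence (`slab_halfwidth_mm = 40`). The axial planes are
  the anatomical boundaries; in-plane, the field of view is split at the
  midsagittal plane to separate the two knees. The half-volume split is a
  package choice for lack of a published in-plane rule; `midline_mm`
  overrides it.
* *hip*: lateral border at the femoral head-neck junction plane, medial
  border 2 mm lateral to the pelvic brim (`brim_margin_mm = 2`),
  superior/inferior borders 10 mm beyond the femoral-neck edge
  (`neck_margin_mm = 10`). This captures the head-acetabulum articulation
  while excluding the neck.
* *sacroiliac*: 20 mm to either side of the articulation line
  (`lateral_margin_mm = 20`), vertically spanning the articulation's own
  extent.

**2. Bone segmentation (`threshold_bone` / `region_grow`)** — voxels with
CT numbers in the inclusive window **150 to 1500 HU**, restricted to the
box. The window keeps cortical and dense trabecular bone and excludes
marrow, soft tissue and metal. Optionally (`grow = TRUE`), only connected
components reachable from seeds at or above `seed_hu = 300` HU are kept
(geodesic dilation to a fixpoint at 26-connectivity), which removes
stray calcifications disconnected from the joint.

**3. Morphological closing (`morphological_close`)** — dilation then
erosion with a **disk of radius 20 voxels applied per axial slice**
(default), pulling the marrow space and subcortical bone enclosed by the
cortical shell into the mask, so the measured region is the whole bony
joint rather than the thin HU-selected shell. The element is clipped at
volume borders (outside counts as background for dilation, foreground for
erosion), which keeps closing extensive, idempotent and monotone — the
three algebraic laws the test suite enforces. A 3D ball element
(`element = "ball3d"`, FFT-based) is available; the slice-wise disk is
the default because it mirrors slice-based workstation practice and its
behavior at slab boundaries is easier to reason about. **The radius is in
voxels**: at the 2 mm study grids it spans 40 mm; proportionally smaller
radii should be used on coarser test grids.

**4. PET-to-CT resampling (`resample_to_grid`)** — trilinear
interpolation in world coordinates onto the CT grid (identity when the
grids already match), zero outside the PET support, error on disjoint
extents.

**5. SUV conversion and averaging** — `activity_to_suv()` then
`global_suv_mean()`. Left and right are quantified separately;
`average_sides()` gives the subject-level statistic used in cohort
correlations.

## Cohort statistics

`cohort_analysis()` correlates every side-averaged uptake column against
every clinical covariate: Pearson r with pairwise deletion, the two-sided
p-value from the t transform \(t = r\sqrt{n-2}/\sqrt{1-r^2}\), and the
least-squares line for plotting. Per-cell n is reported because pairwise
deletion makes it vary. Benjamini-Hochberg q-values per joint-tracer
family are optional (`bh = TRUE`); the primary report is unadjusted, as
is conventional for exploratory correlation tables at this sample size.
Laterality is tested by a classical paired t-test on right minus left,
optionally restricted to right-handed subjects.

`min_detectable_r(n, power, alpha)` solves the Fisher-z sample-size
relation

$$n = \left(\frac{z_{1-\alpha/2} + z_{\mathrm{power}}}{\operatorname{atanh} r}\right)^2 + 3$$

for r by bisection to 1e-6. At n = 18, power 0.8, alpha 0.05 it returns
0.6187, i.e. 0.62 at two decimals. One caveat the validation suite makes
explicit: this is a *planning approximation*. The exact Pearson t-test's
simulated power at r = 0.62, n = 18 is about 0.824, roughly 0.024 above
the approximation's 0.80 prediction — the formula is conservative at
small n.

## What the synthetic data emulate — and what they do not

**Digital joint phantoms** (`make_joint_phantom`) are geometric
primitives: cylinders, spheres and slabs with a cortical shell at 1000 HU
(inside the segmentation window), marrow at 100 HU and soft tissue at 40
HU (both below it), placed symmetrically about the midsagittal plane with
self-consistent landmark files. The PET is built so that converting it
with the phantom's own injection metadata returns the designed SUV field
exactly; the ground-truth mask is the HU rule by construction, so
end-to-end recovery isolates the pipeline's geometric behavior (ROI
cuts, closing bridges, resampling blur) from arbitrary modeling error.
Default grids are 2 mm isotropic (knee 128x128x160, hip 128^3, SI
128x128x96). They emulate: plausible joint-scale geometry, tracer
background (SUV 0.3 FDG / 0.5 NaF), per-side designed uptake, optional
Gaussian PET noise and a coarser PET grid. They do **not** emulate:
partial-volume effects of a scanner PSF, attenuation/scatter artifacts,
anatomical variability, or pathology morphology. Recovery tolerances
reflect this: the 5% end-to-end bound holds at the 2 mm study grids with
the default closing radius; coarser grids need proportionally smaller
radii and show larger discretization error around the thin sacroiliac
cleft.

**Synthetic cohorts** (`make_cohort`) draw from a Gaussian copula: a
latent multivariate normal with a designed correlation matrix mapped
through range-truncated normal marginals whose location is recalibrated
(by root finding) so each variable's *truncated* median matches its
calibration table. The latent correlation is used directly as the Pearson
target — a deliberate approximation; the monotone marginal transforms
attenuate Pearson correlations slightly, empirically well under the 0.04
test tolerance at these truncation levels. Body weight is not a free
marginal: it is derived as `bmi * (height / 100)^2` so weight, height and
BMI are exactly consistent in every table (published cohort medians are
mutually inconsistent in this respect). `default_correlations()` is a
full matrix built from an explicit five-factor loading model, because a
bare list of the reported pairwise values is not positive semi-definite —
BMI correlates with six variables that such a list leaves mutually
independent. Handedness is drawn at the reported 13/18, 4/18, 1/18
frequencies; missingness is completely at random.

## Problem sizes and budgets

The shipped validation runs use: oracle equivalence on volumes up to
20^3 voxels against plain-loop brute-force implementations; 100-200
random masks for the morphology laws; 15 end-to-end phantom recoveries
(three joints, designed SUVs 0.4-4.9) at the 2 mm study grids; 10^4
Monte Carlo replicates for test size and power; and a 12-subject
simulated cohort round trip on 4 mm grids. The full suite runs in well
under a minute of compute-heavy phantom work plus simulation time on one
CPU.
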
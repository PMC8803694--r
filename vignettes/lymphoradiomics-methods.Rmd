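---
title: "Methods: PET radiomics outcome prediction in DLBCL and its synthetic testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PET radiomics outcome prediction in DLBCL and its synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of what it computes and why: the
segmentation and feature definitions, the outcome models and their
evaluation, the synthetic cohort generator that stands in for patient data,
the numerical choices, and the places where the design was genuinely open.
It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The problem

Diffuse large B-cell lymphoma is treated with curative intent, but a
substantial minority of patients progress within two years, and the
clinical International Prognostic Index separates them from the cured
majority only moderately well. Baseline ¹⁸F-FDG PET quantifies the disease
itself: how much metabolically active tumor there is (MTV), how intense the
uptake is (SUV statistics), how far apart the lesions sit in the body
(dissemination), and what shape and internal texture the lesions have. The
package's pipeline asks the canonical question of this literature: do those
image features, alone or added to clinical predictors, improve the
prediction of 2-year time to progression (TTP)?

## Segmentation and quality control

Scans are gated by EANM-style acceptability rules before analysis: the
scan must be complete with essential acquisition metadata present; plasma
glucose must be below 11 mmol/L; and a liver SUVmean outside 1.3–3.0 is
disqualifying when the fraction of injected activity recovered in the
image is also outside 50–80%. That last pair is deliberately implemented
as a *joint* criterion (both must be out of range to fail), because a
liver reference that drifts while total activity is plausible more often
indicates biological variation than a broken SUV calibration; a strict
mode treating the two as independent rules is available via
`qcCheck(strict = TRUE)`.

Lesion delineation mirrors the semi-automated workflow used with
fixed-threshold tools: every 26-connected component of {SUV ≥ 4.0} with
physical volume ≥ 3 mL becomes a preselected lesion; smaller true lesions
are added by a single seed click (`addLesionBySeed`, no volume floor);
physiological uptake is removed wholesale or clipped with a mask
(`removeLesion`, `removeSubregion`). The 3 mL floor applies only at
preselection, not to edited or seed-added lesions. 26-connectivity is the
package's choice — threshold tools rarely document their connectivity, and
26 is the standard for 3-D hot-spot clustering; 6-connectivity is exposed
as an argument. Lesions are labelled in decreasing-volume order with ties
broken by smallest linear voxel index, so segmentations are deterministic
and reproducible byte-for-byte. If a subregion removal splits a lesion,
the fragments become separate lesions and the split is recorded in the
provenance table. Volumes are voxel count × voxel volume on the original
grid throughout.

## Features

**Conventional PET features** (MTV, SUVmax, SUVpeak, SUVmean, TLG =
SUVmean·MTV) are computed on the *original* image grid, per lesion and for
the patient-level VOI (union of lesion masks). SUVpeak is the maximum over
candidate centers restricted to mask voxels of the mean SUV in a 1.0 cm³
sphere around the voxel center; the sphere may extend outside the mask but
not outside the image (border spheres average over their in-image part).
This sphere convention follows harmonization practice; nothing in the
analysis depends on sub-variant details.

**Morphology and texture** are computed on a 2×2×2 mm trilinear resample
(voxel centers corner-aligned, nearest-edge extension at borders; the mask
is carried along by nearest-neighbour resampling), with intensities
discretized at a fixed 0.25-SUV bin anchored at zero:
level(v) = ⌊v/0.25⌋ + 1, so SUV 4.0 falls in level 17.

*Sphericity* is π^(1/3)(6V)^(2/3)/A with V and A taken from the same
triangulated isosurface of the mask: marching tetrahedra at iso-level 0.5
on a 3×3×3 box-smoothed indicator field, volume by the divergence theorem
over the closed outward-oriented triangle set. The smoothing step matters
numerically: a midpoint mesh on the raw binary field is jagged and
overestimates surface area by tens of percent, which would bias sphericity
low for every shape; with smoothing, a digitized 16 mm ball measures
within a few percent of the analytic sphere (asserted in the tests).
The cost is that sharp-edged shapes are rounded — a large cube reads
closer to a ball than its analytic value — an acceptable trade for organic
lesion shapes. Masks thinner than two voxels in some axis cannot support
the mesh and fall back to exposed voxel-face area (flagged; a single voxel
gives the closed-form 0.806). Near-spherical meshes can exceed 1 by mesh
tolerance; values are capped at 1.

*LZHGE* (long-zone high grey-level emphasis) summarizes the grey-level
size-zone matrix: zones are 26-connected components of equal discretized
grey level within the mask, and LZHGE = (1/N_zones)·Σ s(i,j)·i²·j², which
rewards large, hot, homogeneous regions. It is the one texture feature
implemented; the feature table schema is namespaced so further size-zone
or co-occurrence features can be added without format changes.

**Dissemination** is computed from the original-grid SUVmax voxel centers
of each lesion (first in scan order on ties): Dmax_patient (largest
pairwise distance), Dmax_bulk (largest distance from the highest-MTV
lesion), spread_bulk (sum of distances from the bulk lesion), and
spread_patient (sum over *ordered* pairs, i.e., each unordered pair
twice — the literal reading of "from all lesions to all the other
lesions"; `ordered_pairs = FALSE` gives the halved convention). All four
are zero for single-lesion patients, which is also why they are exempt
from the log-transform rule (zeros). Dmax_bulk divided by patient height
(dimensionless, mm/mm) is available as the height-corrected variant.

**Bulky disease** is any lesion whose maximum Feret diameter — the largest
pairwise distance between surface-voxel centers, computed exactly in
chunks — reaches 10 cm.

## Outcome models and evaluation

The primary endpoint is 2-year TTP: progression at ≤ 24 months is an
event; death without progression is censoring at death, so any censoring
before 24 months (death, loss to follow-up, administrative) excludes the
patient from the binary endpoint; everyone else is a non-event. The PFS
sensitivity analysis counts death as an event, so only non-death censoring
excludes. These semantics make the PFS event count ≥ the TTP event count
on any cohort, which the tests assert.

Clinical predictors are dual-coded exactly as the analysis design
specifies (stage III–IV *and* categorical stage; LDH > ULN *and* LDH/ULN;
extranodal ≥ 1 and > 1; WHO ≥ 1 and ≥ 2; age continuous and > 60; bulky
disease), with missing WHO performance status imputed as 0. Six candidate
sets are fitted: IPI alone; the clinical set; MTV alone; the limited
radiomics set (conventional + dissemination + sphericity, patient level);
the lesion-level features of the largest and hottest lesions (LASSO); and
clinical + radiomics combined.

Continuous candidates with sample skewness > 0.5 and strictly positive
values enter as natural logarithms; columns containing zeros are left
untransformed and logged as such. Backward elimination refits after
removing the predictor with the largest Wald p ≥ 0.05 until all survivors
are below 0.05. The removal statistic (Wald rather than likelihood-ratio)
is a package choice the source analysis leaves unstated; at these sample
sizes the two are near-equivalent. Dual coding makes stage's two encodings
*exactly* collinear, so aliased columns are dropped up front and recorded
in the elimination log (`onAlias = "error"` restores a strict failure).
LASSO standardizes to mean 0 / SD 1 and picks its penalty by internal
stratified 5-fold CV at the deviance minimum; coefficients are reported on
the standardized scale with the original-scale back-transform attached.

Discrimination is the Mann–Whitney AUC with DeLong structural-component
variance (implemented in the package and cross-checked in the tests
against both exhaustive concordance counting and an independent library
implementation), and models are compared by the paired two-sided DeLong
z-test. The CV-AUC runs stratified 5-fold splits with the *entire*
procedure — transform and selection — re-fitted inside each training fold;
pooled out-of-fold risks give one AUC per repeat, the mean over repeats is
the CV-AUC and the 2.5/97.5 percentiles its interval. The default is 200
repeats (tests use fewer; 2000 reproduces the full setting at
proportionate cost). Splits that would leave a fold single-class are
redrawn and counted.

Risk stratification fixes the high-risk group size at the number of
observed events among evaluable patients (the prevalence rule; the IPI
model instead uses its 4–5-factor high-risk group) and reports the 2×2
table, sensitivity, specificity, PPV and NPV. When the group size equals
the event count and risks are tie-free, FP = FN forces PPV = sensitivity
and NPV = specificity — an identity worth knowing when reading the
reports, and property-tested. Ties at the boundary are broken by stable
patient order and flagged. Survival contrasts take the top 16% of
predicted risk (all patients, censored included) as the high-risk group,
with Kaplan–Meier curves, the log-rank test, and a univariate Cox hazard
ratio checked for proportional hazards via scaled Schoenfeld residuals.

## The phantom: what it emulates, and what it does not

The generator is the package's study population. Defaults were fixed once,
against the descriptive statistics a first-line DLBCL trial cohort would
show, and are not retuned:

* **Lesions.** Count = 1 + negative-binomial(size 0.9, μ 7) — median
  around 6–8, a long tail into dozens; volumes truncated log-normal
  (meanlog log 18, sdlog 1.1, 4–600 mL), giving total-MTV medians of a few
  hundred mL; lesion peak SUV truncated log-normal (meanlog log 12,
  sdlog 0.5, 5–50), so patient SUVmax medians sit in the low twenties and
  every planted lesion clears the 4.0 threshold. The peak-SUV spread was
  set to reproduce the interquartile range such cohorts report; a narrower
  spread under-identifies the ln SUVpeak effect.
* **Geometry.** Lesion centers are Gaussian around the torso center with
  per-axis sd (0.35, 0.35, 1)·`dissemination_scale_mm` (default 110 mm) on
  a 96×96×192 grid at 4 mm (2 mm supported; 4 mm keeps a full cohort
  renderable in minutes on one CPU). Placement enforces no overlap with
  the liver ellipsoid or other lesions, with at least max(12 mm,
  0.35·(r_i+r_j)) between threshold surfaces; colliding proposals inflate
  the spread and eventually fall back to uniform placement, which also
  makes the degenerate scale-0 configuration feasible.
* **Rendering.** Background N(1.0, 0.12) truncated at 0; liver ellipsoid
  at SUV 2.2 (inside the QC window); each lesion a Gaussian-profile blob
  whose σ is solved so that blob + expected background crosses SUV 4.0 at
  exactly the radius of the nominal volume — the planted super-threshold
  volume is analytic. Outside that radius the profile tapers linearly to
  zero over 6 mm: with unbounded Gaussian tails, a large low-peak lesion
  measurably inflates its neighbours' threshold volumes, and the minimum
  surface separation exceeds twice the taper, so lesions cannot interact.
  The per-lesion digitized super-threshold volume (noise-free) is stored
  as ground truth; segmentation recovery is tested against it at 15%.
* **Covariates.** Tumor burden z = standardized ln MTV (moments frozen
  from a one-off large-sample calibration) drives correlated clinical
  covariates: WHO performance status and Ann Arbor stage as ordinal
  probits on z, LDH/ULN log-normal with mean shifted by z, extranodal
  count Poisson with log-rate in z, age N(65, 11) truncated 20–85
  independent of burden, sex ≈ 1:1, height by sex. Marginals land near the
  usual cohort mix (two-thirds over 60, two-thirds elevated LDH, ~60%
  stage IV, ~45% WHO ≥ 1). No per-patient covariate correlation structure
  is published for such cohorts; these are calibration choices, not facts.
* **Outcomes.** 2-year progression is Bernoulli(expit(lp)) with
  lp = −10.68 + 0.6·ln MTV + 1.0·ln SUVpeak + 0.005·Dmax_bulk(mm) +
  0.8·[WHO ≥ 1] + 0.7·[age > 60]; the intercept was calibrated once so the
  marginal 2-year prevalence is ≈ 16%. Event times are uniform on (0, 24)
  months; non-events receive death-without-progression (4%) or
  loss-to-follow-up (2%) censoring uniform on (0, 24) — both independent
  of the event process, there to make TTP and PFS genuinely different —
  else a 15% chance of late progression (24 + Exp(18) months, capped) or
  administrative censoring at 36 months.
* **Reproducibility.** Per-patient RNG streams are seeded by draws from
  the master cohort stream (`sample.int`), not by arithmetic on the
  cohort seed — streams seeded with consecutive integers are measurably
  cross-correlated, enough to distort pooled-cohort estimates. Identical
  config + seed reproduces a cohort exactly, including the on-disk NIfTI/
  CSV/manifest bytes.

What passing tests on phantoms **does** show: the geometry, feature,
model-fitting and evaluation code is correct against oracles and
recovers planted truth with the right calibration (type-I retention ≈ 5%,
null CV-AUC ≈ 0.5, coefficient consistency). What it does **not** show:
performance on real scans, where reconstruction blur, motion,
physiological uptake, heterogeneous lesion textures and inter-center
effects all live. Real-cohort AUCs and hazard ratios are therefore
neither reproduced nor claimed.

## Numerical choices and degenerate inputs

Problem sizes used by the checks were chosen for desk-scale runtime:
50 imaged patients for segmentation recovery, 25 tabular replicates of
n = 2000 for coefficient recovery (asserted on the pooled estimate, since
a single replicate's Wald SE on a binary covariate is ~0.25), 500
refits of n = 300 for null retention, 8 null cohorts for CV calibration,
and a 100-patient imaged cohort with 50 CV repeats in the acceptance
script. Other notable behaviours: empty masks error; empty segmentations
are legal and flagged `"no FDG-avid lesions"`; a seed click below SUV 4.0
errors; predictions on unseen data clamp log-transformed columns at half
the smallest positive training value so zeros cannot produce infinities;
`delongCompare` of a model with itself returns p = 1 rather than 0/0;
perfect-separation fits are flagged on the result object; and the Cox
contrast reports unestimable when a group has no events.
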
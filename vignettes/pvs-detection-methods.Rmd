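---
title: "White-matter PVS detection and longitudinal analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{White-matter PVS detection and longitudinal analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsmorph)
```

## Scope and model

`pvsmorph` quantifies MRI-visible perivascular spaces (PVS) in cerebral
white matter from a single T1-weighted volume, and analyses how
per-subject PVS burden changes across a longitudinal cohort. The
detector is a local-morphology filter, not a learned model: a PVS is
assumed to be (i) hypointense relative to its immediate white-matter
surround, (ii) locally extreme (darkest few percent of its
neighbourhood), and (iii) tubular (elongated, thin). Nothing in the
pipeline uses atlas priors, vesselness filters, or T2 information, so
the method is deliberately simple, transparent, and restricted to white
matter — T1 hypointensities of other origin inside the mask (lacunes,
white-matter lesions) are indistinguishable from PVS, which is why a
manual review hook (`export_review_table()` / `apply_review_table()`)
exists between clustering and metric computation.

Required inputs are the T1 volume, a brain (skull-stripped support)
mask, and a white-matter mask on the same grid. Producing those masks is
out of scope: any brain-extraction and tissue-segmentation tool can
supply them. Ventricular and total-intracranial volumes enter as scalar
inputs per session.

## Working grid and mask conditioning

All detection runs on a 0.5 mm isotropic grid. `reslice_isotropic()`
maps each output voxel centre to a continuous input index; the output
size per axis is `round(n_in * spacing_in / target)`, aligned to the
input's first voxel centre, so the physical field of view is preserved
to within one output voxel. Intensities are interpolated trilinearly
(exact on constant images); masks use nearest-neighbour, which keeps
them binary. Masks are resliced *before* conditioning so "two voxels"
of dilation/erosion means two 0.5 mm voxels.

`condition_wm_mask()` applies `dilate(2) → fill holes → erode(2)`. The
structuring element is a face-connected (6-neighbour) unit ball applied
iteratively — the most common reading of "by N voxels"; it is a design
choice, since several elements are defensible, and it is deliberately
kept inside one function so an alternative element touches one place.
Hole filling floods the background from the volume border with
6-connectivity; any enclosed background component becomes foreground.
Erosion treats out-of-volume as foreground so masks touching the border
are not eaten from outside. The closing bridges sub-2-voxel gaps and
removes segmentation cavities; the final erosion pulls the mask off
tissue boundaries to avoid partial-volume voxels.

## Candidate criteria and their parameters

For a voxel `v` in the eroded white-matter mask, two neighbourhood
statistics are computed over spherical voxel sets (`sphere_offsets()`:
all integer displacements whose physical length is at most the radius,
boundary inclusive, distances between voxel centres):

| parameter | default | units | role |
|---|---|---|---|
| `rank_radius_mm` | 3 | mm | sphere for the intensity-rank criterion |
| `contrast_radius_mm` | 4 | mm | sphere for the percent-contrast criterion |
| `contrast_threshold_pct` | 15 | % | minimum deficit vs. surround mean (strict >) |
| `rank_percentile` | 5 | % | rank cut-off (fraction of darker neighbours ≤ 5%) |
| `min_cluster_volume_mm3` | 1 | mm³ | cluster volume rule (strict >; ≥ 9 voxels at 0.5 mm) |
| `max_width_mm` | 16.41 | mm | width constraint (strict <) |
| `min_linearity` | 0.8 | – | elongation constraint (inclusive ≥) |

Three decisions the criteria leave open were fixed as follows and are
kept configurable behind `pvs_criteria()`:

* **The centre voxel is excluded** from both neighbourhoods.
  "Surrounding voxels" argues for exclusion, and including the centre
  biases both statistics toward non-detection (the centre would lower
  the surround mean and always count in its own rank).
* **Contrast denominator**: the deficit is expressed relative to the
  *surround mean*, `100 (m − I(v))/m`, not the centre intensity. Only
  hypointense voxels (positive deficit) can pass, matching a detector
  that searches for dark structures.
* **Rank ties**: neighbours exactly equal to the centre do not count as
  darker. Strict counting is deterministic and conservative — a voxel in
  a perfectly flat region has rank 0 but contrast 0, so it is still
  rejected by the joint criteria.

Neighbourhood support is the *brain* mask, not the white-matter mask:
local statistics are computed on the skull-stripped image before the
mask-membership criterion is applied, so white-matter voxels near the
mask boundary see their true anatomical surround. Neighbourhoods are
truncated at the volume border (no padding); a voxel with an empty
neighbourhood or non-positive surround mean gets `NA` statistics and is
never a candidate.

The voxelwise statistics, 26-connected component labelling, and hole
filling are implemented in C++ (`src/pvs_ops.cpp`) because they are the
only voxel-loop hot spots; every other stage is plain R. The test suite
re-implements the criteria, the sphere enumeration, the covariance
descriptors, and the ICC decomposition as independent R loops and checks
exact agreement.

## Shape descriptors

Cluster shape comes from the eigen-decomposition of the covariance of
voxel-centre physical coordinates (population covariance; the
normalisation cancels in all reported ratios). With eigenvalues
`l1 ≥ l2 ≥ l3`, linearity is `l1/(l1+l2+l3)`: 1 for a perfect line, 1/3
for an isotropic blob, so the 0.8 threshold selects strongly elongated
structures. An alternative elongation score (`1 − l2/l1`) was
considered and rejected for the default because it saturates for
thin sheets, which should *fail* a tubularity filter. Length and width
are the extents of the voxel projections onto the first and second
principal axes plus one voxel edge, so a single voxel has physical size
(a single-voxel cluster is defined to have linearity 1 and
length = width = one edge; the edge is the geometric mean of the
spacing, i.e. exactly the edge on the isotropic working grid). The
width entering the 16.41 mm filter is the same width reported as a
session metric; that threshold is inherited from the detector's prior
calibration and is configuration, never hard-coded at call sites.

Medians over an even number of clusters are the mean of the two central
order statistics. Sessions with zero detected PVS report totals of 0
and *missing* medians — propagating `NA` rather than 0 forces
downstream models to drop those sessions explicitly.

## The synthetic phantom

`phantom_truth()`/`render_phantom()` build a box-shaped white-matter
compartment inside a larger uniform brain support, implant tubules
(voxels whose centre is within `radius_mm` of a centreline segment;
point-to-segment distance) at intensity `I_wm (1 − contrast)`, and add
Gaussian scanner noise seeded for bit-reproducibility. Gaussian rather
than Rician noise is used deliberately: at the high signal-to-noise of
white matter on modern T1 acquisitions the Rician distribution is
effectively Gaussian, and a Gaussian keeps the ground-truth contrast
exactly interpretable. Default conditions are the regime the detector
targets: white-matter intensity 100, noise SD 2 (2% of tissue signal),
tubule contrasts 0.25–0.4, radii 0.5–1 mm, lengths 3–10 mm, plus
isotropic blob distractors (radius 1.5 mm, contrast 0.3) that pass the
voxelwise criteria but must be rejected by the linearity constraint,
and sub-threshold tubules at 10% contrast that must never pass the 15%
criterion.

What the phantom does **not** emulate: gyral anatomy and tissue
boundaries (the surround is uniform), bias fields, partial-volume
mixtures at tubule edges, anisotropic acquisition blur, and the
basal-ganglia/ventricular structures that cause the real detector's
false alarms. Passing phantom recovery therefore demonstrates that the
implementation realises the stated criteria and that the geometry
pipeline is correct — not that clinical accuracy equals the phantom
numbers.

`score_detection()` matches a detected cluster to a tubule when its
centroid is within 1 mm of the centreline; recall is over tubules,
precision over clusters, and matched pairs contribute absolute length
and width errors against the nominal tubule size (centreline length +
2 radius, and 2 radius).

## The cohort simulator

`simulate_cohort()` works at the metric level: per subject a latent
baseline per metric, plus a group-specific shift applied from the first
post-flight session onward, plus independent Gaussian session noise.
Controls have no session effects. Defaults encode the study design the
statistics layer expects — 9 novice and 6 experienced astronauts
(sessions L-180, L-60, R+4, R+30, R+90, R+180), 11 controls (four
sessions), age/sex/mission-duration/scan-delay/prior-flight covariate
distributions at realistic values, SANS labels for 12 of 15 astronauts
— and post-flight shifts with the signature the field reports: novices
gain total PVS volume and number, experienced crewmembers lose some,
ventricles expand in everyone. Baseline SDs and session-noise SDs are
set so the totals are highly reliable while the median metrics are
moderate and median width is borderline, reproducing the reliability
*structure* (not the exact values) real cohorts show. Metrics are
simulated independently of each other; real PVS metrics are correlated,
which matters for none of the marginal analyses implemented here but
would matter for joint modelling.

`simulate_image_cohort()` is the image-level analog for end-to-end
smoke tests: per subject one fixed random phantom rendered at two
sessions differing only in the noise realisation — a test-retest pair
for the full detection pipeline.

## Statistics layer

* **ICC(3,k)** (`icc3k()`): two-way mixed, consistency, average
  measures, `(MS_R − MS_E)/MS_R` from the subject × session
  decomposition (mean squares via `aov`), complete cases only; `NA`
  when the decomposition is degenerate. The gate retains a metric only
  when ICC ≥ 0.5 in *both* the astronaut pre-flight pair (k = 2) and
  the control four-session table (k = 4); gated metrics never reach a
  model and the exclusion list is reported.
* **Change models** (`prepost_delta()`, `fit_change_model()`,
  `stepwise_aic()`): Δ = R+4 − L-60 with a logged single-baseline
  (L-180) fallback; intercept-only least squares is exactly the
  one-sample t-test of the mean change; the stepwise search runs both
  directions from the full model with `stats::step`, whose AIC for
  linear models is the Gaussian least-squares form
  `n log(RSS/n) + 2p` (absolute AICs are convention-dependent; only
  within-search differences matter). Totals and ventricular volume are
  modelled on their normalized scales; medians raw. Shapiro residual
  normality accompanies every fit. No multiple-comparison correction is
  applied anywhere; all raw p values and CIs are emitted.
* **Correlations** (`experience_correlations()`,
  `ventricle_correlations()`): Pearson r with df = n − 2; partial
  correlation controlling age by residual-on-residual (df = n − 3);
  reduced-model-first logic — the covariate-adjusted stepwise model is
  fitted only when the reduced relationship is significant at 0.05. A
  subject with a single available baseline contributes that session as
  its "baseline average", logged.
* **Demographics** (`group_contrasts()`): Welch (unequal-variance)
  two-sample t for continuous covariates — the default flavour of the
  analysis environments this design is usually run in — and Pearson
  chi-square without continuity correction for sex. Degenerate
  (constant) variables yield `NA` rows rather than errors.
* **SANS contrast** (`run_sans_contrast()`): the same machinery with
  SANS status replacing experience status; unknown-status subjects are
  excluded and counted.

## Numerical choices and degenerate inputs

Sphere membership uses an inclusive boundary with a 1e-9 mm² slack on
the squared distance so exact-radius voxels are kept deterministically.
Cluster relabelling is scan-order, so label maps are reproducible.
Eigenvalues are clipped at zero before forming ratios; a zero-variance
cluster (single voxel) takes the defined limits. Zero-variance outcomes
fit with SE 0 and are flagged by the degenerate Shapiro/t behaviour
rather than erroring. Rank-deficient designs error naming the collinear
columns. `fit_change_model`/`stepwise_aic` require n ≥ parameters + 2.
All file outputs are written without timestamps and with fixed numeric
formatting; together with seeded RNG this makes every pipeline stage
bit-reproducible, which the test suite asserts end-to-end.

## Problem sizes

The shipped tests and the acceptance script run on 48³ phantoms (20 per
batch), image cohorts of 3–8 subjects × 2 sessions, and 500-replicate
cohort simulations — sizes chosen so the whole suite completes in about
a minute on one CPU while keeping Monte-Carlo error on the reported
rates near one percentage point. The statistical-recovery expectations
(group-coefficient sign recovery and stepwise retention of the group
term at a one-pooled-SD contrast with n = 9 + 6) were fixed in advance
by an independent 4000-replicate Monte-Carlo oracle of the same design;
the tests assert the package reproduces those rates within Monte-Carlo
tolerance.

## Known limitations

The detector is white-matter-only and cannot separate arterial from
venular PVS, nor PVS from other T1 hypointensities without review. The
sub-3 mm diametric definition of a PVS is *not* enforced as an explicit
width filter — the criteria operate indirectly through contrast,
percentile rank and the morphological constraints — so unusually wide
tubular hypointensities below 16.41 mm would survive; this mirrors the
detector the package reimplements and is surfaced here rather than
silently "fixed". Phantom validation bounds implementation correctness,
not clinical accuracy. The cohort simulator's independence assumptions
are stated above. The longitudinal model is a single pre/post
difference; full six-session trajectories (mixed-effects) are out of
scope.
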
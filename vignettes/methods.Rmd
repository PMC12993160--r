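---
title: "Benchmarking thalamus segmentation: models, metrics and the synthetic phantom cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking thalamus segmentation: models, metrics and the synthetic phantom cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thalavol)
```

## The problem

Thalamic atrophy is an established imaging biomarker of neurodegeneration in
multiple sclerosis and related neuro-immunological diseases. Automated
segmentation methods that extract thalamus volumes from MRI differ in
systematic bias, dynamic range and spatial error, and these differences
propagate into the clinical associations fitted downstream. `thalavol`
implements the full evaluation chain for such methods — mask handling,
multi-contrast fusion, voxel-wise and volumetric agreement statistics
against a reference segmentation, longitudinal volume-change extraction and
covariate-adjusted clinical models — together with a synthetic phantom
cohort whose every parameter is known, so each stage can be validated by
parameter recovery. Real single-centre patient data of this kind are
typically confidential; the phantom cohort is the package's test bed, not a
substitute for validating a segmenter on real brains.

## Masks, grids and volumetry

All voxel-wise computation happens on `binary_mask` objects tied to an
`image_grid` (shape, voxel dimensions, 4x4 affine). Voxel volume is the
absolute determinant of the affine's 3x3 block rather than the header
pixdim fields, because pixdim can disagree with the affine after
reorientation; structure volume is foreground count times voxel volume
(1 mL = 1000 mm³). Grid equality is enforced before any pairwise operation,
with a 1e-4 mm tolerance on affine entries to absorb round-trip float
noise. The package deliberately does not resample between grids — inputs
are expected to be registered to a common reference beforehand.

Method-specific label conventions (e.g. left/right labels 10/49 in an
aseg-style scheme, or the set 24–27, 30, 31 in a deep-brain labelling) are
captured as `label_scheme` objects; `extract_mask()` merges the scheme's
labels into one bilateral mask. Empty masks are representable and flagged,
never silently dropped, because the agreement metrics define explicit
conventions for them.

## Harmonization and registration QC

`rescale_quantitative_map()` harmonizes a quantitative map (such as an R1
relaxation-rate map) with T1-weighted intensities: in-brain values are
clipped at the 99th percentile and mapped linearly onto [0, 1000], voxels
outside the brain mask are set to exactly 0. The mapping is monotone, so
rank order is preserved and no histogram-matching artefacts are
introduced. The lower anchor is the in-brain minimum — "rescaled to a
0–1000 range" implies the minimum maps to 0.

Registration quality control uses joint-histogram mutual information
(equal-width bins over the masked intensity range, 64 bins, natural log).
The estimator was chosen for transparency; MI cut-offs (defaults 0.25 for
an FSL-type strategy, 0.30 for an ANTs-type strategy) are in the units of
*this* estimator and must be recalibrated per deployment — published
cut-offs from other estimators do not transfer. `select_registration()`
implements the deterministic rule: best passing candidate of the primary
family, else the alternate family's passing candidate, else exclusion;
ties break by candidate order, and a manual visual-review flag can force
exclusion regardless of the metric.

## Label fusion

`majority_vote_fusion()` marks a voxel foreground when the mean of the
input indicator masks is `>= threshold`. The `>=` comparison is
load-bearing: at the default threshold of 0.5 it yields the **union** for
two inputs and the 2-of-3 **majority** for three, which is exactly the
intended ensemble behaviour for 2- and 3-contrast mask sets. Equivalently
a voxel needs at least `ceiling(threshold * k)` votes; the test suite
verifies this by exhaustive enumeration of all membership patterns for
k ≤ 4. No morphological cleanup follows fusion: when a composite label
bridges into a neighbouring structure, the correct tool is
`isolate_structure()`, a voxel-wise AND with a structure-specific envelope
mask, not thresholding or connected components.

## Agreement statistics

Spatial agreement is computed from voxel counts: DSC = 2TP/(2TP+FP+FN),
precision = TP/(TP+FP), sensitivity = TP/(TP+FN). Degenerate conventions
are fixed and flagged: both masks empty gives all three metrics 1; an
empty prediction (or reference) gives 0 for the affected metrics. The
directed containment coefficient |Mi ∩ Mj|/|Mi| is computed per subject
and then averaged; it equals sensitivity with Mi as reference, an identity
the tests check numerically. Summaries are medians with 25th/75th
percentile IQRs; method pairs are compared with paired two-sided Wilcoxon
signed-rank tests (zero differences dropped, exact distribution for ≤ 25
non-zero pairs, otherwise normal approximation with continuity
correction), Benjamini–Hochberg adjusted. BH families are kept per
analysis table; the correction is an explicit step-up implementation,
cross-checked against `stats::p.adjust` in the tests.

Volumetric agreement of paired (reference, method) volumes comprises:

* **Lin's concordance correlation coefficient**
  ρc = 2Sxy / (Sx² + Sy² + (x̄ − ȳ)²), with population-form (1/n) moments
  and a Fisher-z confidence interval using Lin's asymptotic variance.
* **ICC(3,1)** from the two-way mean-square decomposition with the
  reference and one method as the two fixed raters. The consistency form
  (MSR − MSE)/(MSR + MSE) is primary; the absolute-agreement form is also
  returned because the two conventions are often conflated in applied
  reports, and they differ exactly when the raters' means differ.
* **Calibration regression** y = α + βx (method on reference): β is a
  dynamic-range indicator (β = 1 ideal), the residual SD (mL) a precision
  metric.
* **Bland–Altman analysis** with the *method − reference* sign convention,
  so positive mean bias means over-segmentation. Limits of agreement are
  mean ± 1.96 SD (1.96 fixed, not configurable); proportional bias is the
  OLS slope of differences on pair means with its 95% CI.

One estimand subtlety matters for recovery testing: if a simulated method's
volume error is `b + s·(x − x̄) + ε` *on the true volume x*, the
calibration slope estimates 1 + s without bias, whereas the Bland–Altman
d-on-mean slope estimates a different, noise-shifted quantity (the classic
artifact of regressing differences on means when error sits in one method
only). The recovery tests therefore check the additive bias via the BA mean
bias and the proportional component via the calibration slope; the BA slope
is recovered exactly in simulations that generate differences on the means.

## Clinical association models

Cross-sectional models are OLS of a clinical outcome on one method's
volume, adjusted for age (years), sex and z-standardized intracranial
volume (population-SD convention, configurable). Right-skewed timed tests
(T25FW, 9HPT) are natural-log transformed, so the volume coefficient reads
approximately as fractional change per mL. Heteroscedastic outcomes (EDSS)
use HC3 robust standard errors; the acceptance suite reproduces the
rationale by showing HC3 keeps ≥ 92% empirical coverage under variance
proportional to the squared fitted mean while remaining nominal under the
null. Longitudinal models regress the clinical delta (year 1 minus
baseline) on the volume delta in mL (percent is supported; mL is the
default because the coefficient reads per-mL), additionally adjusted for
inter-session corticosteroid treatment and the inter-scan interval.
Missing data are handled complete-case per model. No mixed-effects
modelling is used: segmentation is per-timepoint and the deltas are simple
differences by design.

Two sensitivity analyses accompany the longitudinal EDSS model:
winsorization of the volume deltas at 1–99% and 5–95% (inverse-ECDF
quantiles, so the operation is idempotent), and a proportional-odds model
of EDSS-change categories. The categories — worsened (Δ ≥ +0.5), stable,
improved (Δ ≤ −0.5) — follow the conventional clinical cut at the EDSS
half-point step and are configurable, since no canonical definition
exists. Complete separation in the ordinal model is caught and flagged
rather than reported as a fit; no penalized ordinal estimator is shipped,
so a flagged result simply directs the analyst back to the OLS direction
check.

## The synthetic phantom cohort

The generator is first-class, tested code: its role is to give every
pipeline stage a recoverable truth.

**Ground truth.** Bilateral ellipsoids (default grid 96³ at 0.8 mm
isotropic, semi-axes 6.5 × 16 × 10.5 mm per side, centres ±11 mm) scaled
per subject so the analytic volume matches a draw from N(9.13, 1.89²) mL
truncated at 3 SD — the distribution of reference-standard manual thalamus
volumes in an MS population. A smooth random radial perturbation (4
random-phase low-frequency sinusoids, 5% amplitude) keeps boundaries
non-analytic; amplitude 0 recovers the exact ellipsoid, which the tests
compare to the closed-form volume. Decoy regions — a medial "ventricle"
slab and a lateral "caudate bridge" — are labelled so that over-segmenting
profiles have anatomy-like places to spill into and envelope-intersection
has something to remove.

**Simulated segmenters.** A profile's expected volume is
`true + bias + slope·(true − cohort mean)`, achieved exactly by iterative
single-voxel-layer dilation/erosion with random partial-layer selection
(continuous volume control on a discrete grid). Spatial error styles:
*dilate-into-decoys* keeps the truth contained (sensitivity ≈ 1, low
precision — atlas-like over-segmentation); *erode-uniform* and *balanced*
additionally resample a fraction of the boundary (`jitter_frac`), a
volume-preserving swap of inner- and outer-boundary voxels that makes the
mask spatially distinct from the truth (CNN-like). Jitter is applied after
volume targeting because dilation would otherwise refill the holes it
punches. Note one geometric constraint: precision > sensitivity is only
attainable when the expected volume is below the truth — a method that
over-segments on average necessarily has precision below sensitivity.

Volume noise is specified in boundary-layer units (one unit ≈ the volume
of a one-voxel shell, ≈ 2.1 mL for the default phantom) and is split into
a subject-level component that persists across timepoints and a small
session component (default 0.06 layers ≈ 0.13 mL). The split reflects how
segmenters err on real data: the same anatomy is mis-measured the same way
at both visits, so cross-sectional scatter is large (≈ 1.4–1.6 mL) while
longitudinal percent-change noise stays near 2% — without the split,
simulated one-year deltas would be an order of magnitude noisier than
anything observed in practice.

The three default profiles are anchored to published benchmarking
behaviour: `atlas_like` (bias +5.65 mL, slope +0.28, FreeSurfer-like),
`cnn_compressed` (bias +0.75 mL, slope −0.43, DBSegment-like dynamic-range
compression), `balanced` (bias +1.11 mL, slope −0.09, MindGlide-like).
Jitter fractions (0, 0.95, 1.35) were calibrated once so the baseline
Dice/precision/sensitivity medians of the three styles reproduce the
published per-method pattern; they are generator design constants, not
free dials.

**Cohort.** Demographics follow the emulated population: age 43.4 ± 12.4
years, two-thirds female, diagnosis mix dominated by relapsing-remitting
MS with a small healthy-control fraction. True volumes are confounded with
age (−0.03 mL/year) and ICV (+0.8 mL per z) by construction, so the
covariate adjustment in the clinical models is load-bearing. Atrophy rates
are −0.5 ± 0.4 %/year for patients and 0 ± 0.2 for controls, applied by
exact-count boundary erosion; a PBVC-like global-atrophy variable
(−0.32 ± 0.55%) is generated with correlation 0.5 to the realized thalamic
rate. Clinical outcomes come from the same linear models the analysis
fits: EDSS (volume coefficient −0.26 per mL, snapped to the 0–10
half-point lattice after generation; pre-snap values stay in the truth
ledger so exact-recovery tests remain possible), log-normal timed tests,
SDMT (+2.6 per mL), and delta outcomes driven by the measured ground-truth
volume change (ΔEDSS coefficient 0.6 per mL). All randomness flows from
one seed; identical configurations give identical cohorts.

## What passing tests do and do not show

The phantoms have smooth convex-ish shapes, additive Gaussian volume
noise, stationary bias and no intensity information at all. Passing
recovery tests therefore demonstrates that the *statistics* are computed
correctly and that the pipeline's inferences are faithful when its model
assumptions hold — not that any real segmenter behaves like a profile, nor
that registration, lesion effects, scanner drift or pseudoatrophy are
handled. The MI module in particular only evaluates alignment quality; it
never estimates a registration.

## Problem sizes and numerical choices

The shipped test suite exercises: 200 random 16³ mask pairs against a
set-arithmetic oracle; exhaustive fusion enumeration for k ≤ 4; 100 random
50 × 2 tables against a two-way ANOVA oracle (1e-10); 200-replicate
Bland–Altman recovery at n = 50; 500-replicate HC3 coverage at n = 300;
and one seeded end-to-end cohort of 50 phantoms × 3 methods × 2
timepoints on the default 96³ grid. The acceptance script runs the same
end-to-end study plus a 321-subject volume-level cohort for the clinical
models, mirroring the two-cohort design (small reference-standard
sub-study, larger full analysis set) such evaluations use. Unit tests use
a smaller 1 mm phantom for speed; the statistics are grid-agnostic.

Numerical conventions collected in one place: CCC uses 1/n moments;
ICC CIs are F-based; LoA multiplier fixed at 1.96; quantiles are type 7
(linear interpolation) everywhere except winsorization (type 1, for
idempotence) ; MI uses 64 equal-width bins and natural logs; fusion uses
`>=` at the threshold with a 1e-12 guard against float error; grid
tolerance 1e-4 mm; EDSS snapping rounds to the nearest half point.

## Known limitations

No resampling or reorientation; no surface-distance metrics (Hausdorff,
ASSD); no probabilistic (STAPLE-style) fusion; no repeated-measures
Bland–Altman; no penalized ordinal regression fallback; the MI cut-off
defaults are placeholders until calibrated on the deployment's own
estimator; and the generator does not simulate MR intensities, lesions or
the internals of any deep-learning segmenter.
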
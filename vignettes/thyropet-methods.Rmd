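---
title: "Models and methods behind thyropet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind thyropet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thyropet)
```

`thyropet` analyses FDG-PET/CT in cytologically indeterminate thyroid
nodules along two arms: a rule-out threshold analysis of SUV metrics, and a
radiomic classifier on segmented nodule volumes. This vignette documents the
models, the tunable parameters with their defaults and rationale, the
numerical choices, and what the synthetic data can and cannot establish.

## The synthetic cohort and phantom generator

No patient images ship with the package, so every downstream stage is
exercised on simulated data whose statistical structure mirrors the study
conditions the analysis assumes.

**Cohort structure.** `cohort_config()` defaults to 123 cases with cytology
counts 55/39/29 (AUS/FLUS, FN/SFN, HCN/SHCN) and group-wise
malignant/borderline prevalence 24/94 in the non-Hürthle groups and 9/29 in
the Hürthle group, which reproduces the overall 27% (33/123) rate.
Group and label counts are apportioned by largest-remainder rounding, so a
fixed configuration yields fixed counts; multinomial/binomial sampling is
available via `allocation = "sampled"` when sampling variability itself is
under study.

**SUV distributions.** Published SUV summaries are medians with
interquartile ranges, per outcome stratum. SUVs are positive and
right-skewed, so each (cytology group, label) stratum draws nodule SUVmax
and background SUVmax from log-normal distributions. A two-parameter
log-normal cannot reproduce an asymmetric (Q1, median, Q3) triple exactly,
and the three-parameter (shifted) fit that could would place probability
mass on negative SUVs for these inputs. `fit_lognormal_from_median_iqr()`
therefore matches the median exactly (`mu = log(median)`) and root-finds the
`sigma` whose interquartile *width* equals the published `Q3 - Q1`; the
round-trip of median and IQR width is tested to `1e-6`. SUVpeak is drawn as
a Beta-distributed fraction of SUVmax (shape `c(24, 6)`, mean 0.8,
matching the published peak/max ratios of roughly 0.73–0.85), which
guarantees `suv_peak <= suv_max`.

**Visual positivity.** Visual FDG-positivity is a contrast judgement against
the surrounding normal thyroid; the simulator models it as the rule
`suv_max / background_suv_max > 1 + eps` with `eps = 0.1` (configurable).
With the default calibration this yields about 69% visually positive cases —
close to the 68% the analysis design anticipates — but the fraction is
emergent, not fitted. In imaging mode, a case whose *measured* post-blur
peak does not exceed the measured background is reclassified as visually
negative and excluded from radiomics with a log entry, mirroring the
clinical definition.

**Phantoms.** `generate_phantom()` builds an ellipsoidal uptake region of
amplitude `peak_suv` over `background_suv`, multiplies the nodule contrast
by a band-limited texture field (Gaussian-filtered white noise, correlation
length 6 mm, amplitude a configurable fraction of the contrast, default
0.15), convolves the scene with a Gaussian PSF (default FWHM 7 mm, typical
of EANM-conformant whole-body PET), and adds Gaussian noise (default SD 5%
of background; Poisson-like noise is out of scope). The matching low-dose
CT volume places the nodule (default 45 HU) over soft tissue (40 HU). The
default grids — PET 3.18 mm, CT 1 mm isotropic — make the later
interpolation targets (4 mm / 2 mm) non-trivial. Increasing the texture
amplitude strictly increases pre-noise within-mask variance, which the
tests assert.

**What passing tests show.** The phantoms validate the *mechanics* of
quantification, segmentation, feature extraction and evaluation, and the
calibration of the statistical machinery (interval coverage, null behaviour,
parameter recovery). They do not emulate scanner reconstruction, respiratory
motion, multi-nodule glands or inter-scanner heterogeneity, so passing tests
say nothing about classifier performance on real patients.

## SUV quantification

SUVmax is the maximum voxel value in the region; SUVpeak the maximum, over
candidate sphere positions, of the mean of voxels whose centres lie within a
1 mL sphere (diameter ≈ 12.4 mm). Membership is by voxel-centre inclusion
without partial-volume weighting, and candidate centres are voxel centres
whose sphere touches the region — the sphere may extend beyond the nodule,
consistent with the standard SUVpeak definition. These conventions are
deliberately simple and deterministic so that an exhaustive brute-force
oracle can check them exactly. Background SUVmax comes from a contralateral
region; in phantom mode this is the nodule box mirrored across the
mid-sagittal plane with any overlap with the nodule box removed. Ratios are
kept at full precision internally and rounded to one decimal only for
presentation. Volumes are assumed already body-weight-normalised to SUV;
the package never converts raw activity.

## Segmentation

`segment_nodule()` computes SUVpeak inside an axis-aligned box around the
nodule locator (margin 1.5× the stated size, to exclude surrounding
FDG-positive tissue) and thresholds at

> `T = background + 0.5 * (SUVpeak - background)`,

keeping the 26-connected component (voxels `>= T`, ties included) that
contains the in-box SUVmax voxel. The cited background-correction method is
not printed in full anywhere accessible, so the additive reading
`T = 0.5 * SUVpeak + background` is provided behind `method = "additive"`
and the choice is recorded in the mask provenance; no claim is made that
either exactly reproduces the study's masks. The threshold is scale
equivariant (scaling the image and background by `c` leaves the mask
unchanged) and monotone in the background, both property-tested. On
noise-free blurred-sphere phantoms the mask boundary sits within one voxel
of the analytic isocontour radius, replacing the study's visual mismatch
check with an automated one.

The low-dose CT VOI is the PET VOI resampled by nearest neighbour. Exact
half-way ties in that mapping are broken consistently toward +infinity;
`round()`'s banker's rounding would alternate tie directions on nested 2:1
grids and distort mask volumes. The 64-voxel minimum-size recommendation is
implemented as a flag (`check_min_voxels()`), surfaced in the pipeline
manifest.

## Radiomic features

Volumes are trilinearly interpolated to isotropic grids (PET 4 mm, CT 2 mm)
and discretised with fixed bin widths (PET 0.5 g/mL, CT 25 HU), with bin
edges anchored at the in-mask minimum. Edges are built by accumulation and
assigned with `findInterval()`, because `floor((x - min)/width)` misbins
values that land exactly on an edge after floating-point subtraction.

The feature set is frozen in `feature_manifest()`: 107 features per
modality (14 shape, 18 first-order, 24 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM,
5 NGTDM), following the catalogue of the standard extraction tools; PET
additionally carries TLG = SUVmean × MTV. Any drift of names or counts from
the manifest is an error, not a warning. Conventions:

* GLCM and GLRLM use the 13 unique 3-D directions at distance one voxel,
  symmetric co-occurrence, feature averaged over directions; GLSZM and GLDM
  use 26-connectivity; NGTDM the 26-neighbourhood. Direction-averaged
  features are invariant to axis flips and 90° rotations (tested).
* GLDM dependence counts the centre voxel as dependent on itself
  (`j = 1 +` qualifying neighbours, `alpha = 0`), avoiding an empty
  dependence class.
* Degenerate inputs follow fixed conventions rather than NaN: a constant
  VOI has GLCM correlation 1 and NGTDM coarseness `1e6`; a single-voxel
  mask returns shape features and flags all intensity/texture features `NA`
  with a warning (undefined, never silently zero).
* Logs use a machine-epsilon guard, matching reference implementations.

**Shape features and the mesh.** Surface area, mesh volume and sphericity
come from a marching-tetrahedra triangulation (six tetrahedra per cell,
vertices linearly interpolated on edges) of the mask indicator smoothed
with a Gaussian of one voxel SD. Meshing the *binary* mask at iso-level 0.5
— as some tools do — leaves a staircase whose area never converges: a
digitised sphere then gets sphericity ≈ 0.91 under marching cubes (≈ 0.78
under marching tetrahedra) at any resolution. Meshing the anti-aliased
indicator restores convergence; a digitised sphere at 1 mm spacing scores
sphericity within 2% of 1 in the tests. The smoothing slightly rounds sharp
corners and shrinks the mesh volume of small objects by a few percent
(voxel-counting volume is reported separately, and MTV/TLG always use voxel
counting). VOIs too small to survive smoothing (about one voxel across)
fall back to the binary-surface mesh. Maximum 3-D and in-plane diameters
are computed on boundary voxel centres (in-plane variants grouped by
slice/column/row); principal-axis lengths are `4*sqrt(lambda)` of the
voxel-coordinate covariance, with elongation and flatness as the usual
ratios.

Cross-checks against the reference Python extraction tool were not possible
in this build (it is not installable here); the texture matrices are instead
verified against independent brute-force enumerations of pairs, runs and
zones (the zone oracle uses igraph components), and shape features against
analytic spheres.

## Dimensionality reduction

Each training split is standardised (training means/SDs), redundancy
filtered, and factored:

* `redundancy_filter()` greedily removes the feature with the most
  super-threshold partners (`|r| > 0.9` by default; the threshold is a
  logged configuration item, chosen as the customary high-correlation
  filter) with ties broken by feature name, so results are deterministic.
  Constant features are removed first with a warning.
* `reduce_dimension()` additionally continues the greedy removal — dropping
  the feature with the largest mean absolute correlation — until the number
  of features is at most `n_train - 2`. Maximum-likelihood factoring needs a
  well-conditioned training correlation matrix; with radiomic feature sets
  (hundreds of features, dozens of cases) this continuation is what makes
  per-split refitting feasible. At the study's scale (68 training cases) the
  0.9 filter alone usually suffices.
* `fit_factor_model()` runs maximum-likelihood factor analysis
  (`stats::factanal`) on the training correlation matrix with varimax
  rotation, `max(1, floor(n_train/10))` factors (68 → 6), factors ordered
  by explained common variance. If the requested count is not identifiable
  for the retained feature count (negative degrees of freedom), it is capped
  at the largest identifiable value. Heywood-prone fits retry with a larger
  uniqueness lower bound (0.005 → 0.01 → 0.05, warning) before erroring.
  Scores use the regression (Thomson) weights `W = R^{-1} L` — the default
  of the factor-analysis ecosystem this follows; Bartlett scores were the
  alternative — with a ridge fallback (`1e-6 I`) if `R` is near-singular.
  Test cases are projected with training statistics only; deleting test
  cases provably changes nothing in the fit (tested by refit comparison).
* `compute_kmo()` reports the Kaiser–Meyer–Olkin sampling adequacy from the
  anti-image of the correlation matrix, ridge-regularising with the smallest
  `lambda` in `10^{-6..0}` that restores invertibility (message logged).
  Factors are reported by their top-loading features (`tidy()`), but the
  package does not name factors semantically — that was an interpretive
  step.

## Classifier and evaluation

The classifier is penalised logistic regression (glmnet) with mixing
parameter `l1_ratio = 0.5` — the study does not print its hyperparameters,
so the balanced elastic net is the default and `penalty_strength` is chosen
by internal 5-fold cross-validation on the training split with
deterministic, class-stratified folds. Both choices are recorded in the fit
object. The intercept is unpenalised and predictors are standardised
internally; at zero penalty the fit matches the unpenalised Newton solution
to `1e-5` (tested).

`repeated_split_eval()` runs `k = 20` random 80/20 splits. Splits are
stratified by outcome: with 27% prevalence and test sets of ~17 cases,
unstratified splits frequently lack positives entirely; stratification is
logged and switchable. The *entire* pipeline — standardisation, redundancy
filter, factor analysis, penalty search — refits on each training split;
the spec-level no-leakage property (a marker feature carrying no training
signal cannot lift the evaluated AUC above the permutation null) is tested.
The summary is the mean test AUC with the corrected resampled *t*-interval

> mean ± t(k−1, 0.975) · sqrt( s² · (1/k + n_test/n_train) ),

using the realised split sizes, clipped to [0, 1]; with zero variance the
interval degenerates to the mean. The correction term makes the interval
strictly wider than the naive resampled-*t* interval whenever the AUCs vary.
Null calibration — 200 label-permuted 84-case cohorts, 20 splits each — is
asserted to cover AUC 0.5 at roughly the nominal rate in the test suite
(the corrected interval is known to be conservative, so observed coverage
sits near the top of the band). AUC itself is the Mann–Whitney rank
statistic with ties at ½, identical to the trapezoidal area under the
empirical ROC curve.

The published real-data AUCs (0.445 all-nodules PET model, 0.519/0.694 in
subgroups) depend on the patient scans and are deliberately not targets:
they are unreachable from synthetic data, and tuning a simulator to hit them
would demonstrate nothing.

## Threshold analysis

Test-positive means `value >= cut_off`; higher uptake is more suspicious
(cut-offs in the published table sit below the malignant medians).
`find_cutoff()` scans the observed values — whether the study selected on
rounded or exact SUVs is unstated, so `rounded = TRUE` selects among
1-decimal candidates instead, and the mode is logged — and returns the
largest cut-off with sensitivity at or above the floor (default 0.95, per
the rule-out NPV recommendation); the largest such threshold also maximises
specificity among equally sensitive ones. All five accuracy metrics use
exact Clopper–Pearson intervals from beta quantiles, with `low = 0` at zero
successes and `high = 100` at full successes; zero-denominator metrics are
reported `NA`. The benign call rate is the fraction of negative tests,
`(tn + fn)/n` — the potential surgery-avoidance yield. The AUC interval
method is not printed in the source material; DeLong is used as the
standard nonparametric choice and is cross-checked against a bootstrap
percentile interval in the tests. Feeding the published contingency counts
through `diagnostic_table_from_counts()` reproduces every printed point
estimate and interval bound to one decimal (tested cell by cell).

## Problem sizes and determinism

The test suite and acceptance script run on deliberately modest problem
sizes — phantom grids of 16³–48³ voxels, cohorts of 18–123 cases (2,000 for
distribution calibration), 200 repetitions for null calibration, 10,000 for
interval coverage — chosen so the full pipeline, including the imaging arm,
exercises every code path in a few minutes on one core. All randomness flows
through explicit seeds; `generate_phantom()`, `generate_cohort()` and
`repeated_split_eval()` restore the caller's RNG state, and identical seeds
give bit-identical outputs (tested).

## Known limitations

* The phantom is a two-compartment scene with stationary Gaussian texture;
  it does not model reconstruction artefacts, scanner heterogeneity,
  respiratory motion, or uptake heterogeneity beyond the texture field.
* The smoothed-indicator mesh biases the mesh volume of small VOIs low by a
  few percent relative to the analytic volume (sphericity is nearly
  unaffected; voxel-counting volume and MTV are exact by construction).
* The in-plane maximum-diameter convention (boundary voxel centres grouped
  per plane) may differ from mesh-vertex-based conventions in other tools
  by up to about one voxel.
* The exact background-correction formula behind the isocontour threshold
  and the study's elastic-net hyperparameters are not printed; both are
  exposed as logged configuration rather than silently fixed.
* Tabular mode carries no radiomic features; the classifier arm requires
  imaging mode (or an externally supplied feature table).
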
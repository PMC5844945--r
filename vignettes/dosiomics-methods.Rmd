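---
title: "Dosiomic NTCP modeling of xerostomia: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dosiomic NTCP modeling of xerostomia: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the science implemented in `dosiomics`: the outcome
and its end points, the feature definitions, the univariate screen, the
multivariate model-building pipeline, the algorithm-comparison machinery,
and the synthetic cohort generator — together with the numerical and design
choices that were genuinely open, and what the tests do and do not show
about real clinical data.

## The modeling problem

Radiotherapy of head-and-neck tumors inevitably irradiates the parotid
glands, the main producers of saliva. Moderate-to-severe xerostomia (dry
mouth, CTCAE grade ≥ 2) is a common, quality-of-life-limiting complication.
Classical NTCP models summarize the insult by the gland mean dose; this
package implements the richer view that the *spatial arrangement* of dose
within the gland and the gland's *geometry* carry additional predictive
information.

The outcome is modeled four ways. Three **time-specific** end points
aggregate follow-up grades in the windows (0, 6], (6, 15] and (15, 24]
months after treatment (early, late, long-term): a patient's grades in a
window are averaged and rounded to the nearest integer, x.5 rounding up,
then binarized at grade ≥ 2. One **longitudinal** end point keeps every
follow-up visit as its own observation, with the time after treatment as a
model covariate. Window boundaries are half-open with the boundary visit
assigned to the earlier window — the choice is arbitrary, so it is fixed
once and documented here.

## Geometry and lateralization

All volumes live on LPS lattices (x right→left, y anterior→posterior, z
inferior→superior; mm). Grids are trilinearly resampled to isotropic
resolution before feature extraction; masks are interpolated the same way
and re-binarized at 0.5, which keeps them binary at the cost of shifting
the digitized surface by up to half a coarse voxel. Masks can alternatively
be rasterized from planar contours (voxel-center, even–odd rule), which is
the path to take when contours are available at the target resolution.

Spatial features must not depend on whether the treated side happened to be
left or right. The package therefore flips all volumes through the sagittal
plane when the right gland's mean dose strictly exceeds the left's, and
then labels the higher-dose gland ipsilateral. Ties do not flip. The flip
reverses the sign of x-odd features (gradient~x~, η with odd p) and leaves
everything else invariant, which the test suite asserts; extraction is
consequently invariant to the original left/right labeling.

## Features

Per gland, 60 features in eight groups (plus demographics):

* **Shape**: volume; surface area; sphericity π^1/3^(6V)^2/3^/A;
  eccentricity sqrt(1 − λ~3~/λ~1~); compactness V/(√π A^3/2^); λ~1~ ≥ λ~2~
  ≥ λ~3~, the eigenvalues of the voxel-coordinate covariance (mm²). The λ
  are covariance eigenvalues, not semi-axis lengths — the two conventions
  differ by a constant factor (a uniform ellipsoid has λ = a²/5) and the
  covariance form is the one that needs no shape assumption.
* **DVH**: mean, spread (population SD), skewness, D2/D98 and the deciles
  D10…D90 (dose received by at least x% of the volume, linearly
  interpolated between order statistics), V10…V45 (volume fraction at ≥ x
  Gy), entropy (bits) and uniformity over fixed 1-Gy histogram bins from 0
  to the maximum dose. Fixed-width bins make entropy comparable across
  patients and resolutions.
* **Subvolume mean doses**: the mask bounding box is cut into three
  equal-width slabs per axis (remainder voxels join the last slab) and the
  mean dose of each slab is reported. With the remainder rule, the sagittal
  flip maps sx1↔sx3 exactly only when the box length divides by three;
  otherwise the slabs differ by the remainder voxels. This is the price of
  a deterministic, simple cut.
* **Spatial dose gradients**: slopes of the least-squares affine fit of
  dose on voxel-center coordinates (Gy/mm) — exact on affine fields.
* **Dose moments**: dose-weighted central moments of the voxel positions,
  scale-normalized as η~pqr~ = μ~pqr~/μ~000~^1+(p+q+r)/3^, for all 16
  second- and third-order index triples. The normalization makes η
  dimensionless against overall dose scale; a translation of the whole
  volume leaves every η unchanged. The morphological reference model uses
  η~111~^i^, η~002~^c^, η~300~^c^ and η~110~^i^·η~110~^c^.

Surface area needs care on voxelized masks: naive exposed-face counting
overestimates a sphere's area by 50%. The package integrates the gradient
magnitude of the Gaussian-smoothed (σ = 1.5 mm) mask indicator — the
coarea formula — which is accurate to about 1% on digitized balls and a few
percent on 2:1 ellipsoids, at the cost of rounding sharp edges (an
axis-aligned cube is underestimated by ~12%; parotid-like smooth shapes are
the intended regime).

**Redundancy filter.** Kendall's τ (tie-corrected) is computed for every
feature pair in both glands; a pair with |τ| > 0.5 in both glands —
concordance probability (1+τ)/2 > 75% — drops its less simple member,
where simplicity is an explicit priority ranking (mean dose before any
DVH-derived dose point; volume before derived shape descriptors). The
ranking is data-independent, so the filter is deterministic and its drop
log is auditable.

## The univariate screen

Features are Z-scored (population SD) and each is tested against the binary
end point with the Mann–Whitney U statistic; AUC = U/(n₋ n₊). Confidence
intervals come from a bias-corrected and accelerated (BCa) bootstrap with
resampling stratified by class, B = 2000 by default (the bias correction z₀
from the bootstrap distribution, the acceleration from jackknife skewness).
P-values use the normal approximation with tie and continuity corrections —
adequate at cohort sizes of about a hundred — and the set of p-values is
controlled by an adaptive step-down FDR procedure with critical constants
c~i~ = iq/(m+1−i(1−q)), q = 0.05. Two-sided p-values are used; the choice
is fixed here since either convention is defensible.

The reported AUC is that of the univariate logistic model, i.e. protective
features (higher value, lower risk — parotid volume is the canonical case)
are orientation-flipped so the table shows discrimination ≥ 0.5 with a
`direction` column; the raw U-statistic convention is preserved in
`mwu_auc()` and the identity AUC = U/(n₋ n₊) holds row-wise after the
consistent flip. Tolerance values invert the univariate logistic fit:
TVp = (logit p − β₀)/β₁ in the feature's original units, so a protective
feature has TV5 > TV10 > TV20.

When R discoveries survive the FDR bound q, treating each as independently
false with probability q yields lower bounds on their joint truth:
(1−q)^R^ that all are true, plus R·q(1−q)^R−1^ for at most one false.

## The multivariate pipeline

Model building is a five-step workflow: (1) Bernoulli feature-group
selection (each group kept with probability ½, empty draws repeated); (2)
Z-scaling; (3) sampling; (4) feature selection; (5) classification. Ten
sampling options are enumerated — the nine named cleaning/balancing
algorithms plus explicit no-sampling, which is what reconciles the
7 × 7 × 10 = 490 configurations per end point (1,960 over four end points)
— and the package treats "none" as a first-class option. All fold-local
statistics (scaling means/SDs, sampler neighborhoods, selector rankings)
are computed on the training fold only; the tests assert the absence of
leakage rather than assuming it.

Tuning is random search: 300 hyperparameter draws by default, each scored
by cross-validated AUC — stratified Monte Carlo CV (300 splits, 10% test)
for time-specific end points, and for longitudinal data a modified
leave-pair-out CV in which each split tests one positive and one negative
observation from different patients and *removes every training observation
sharing a patient id with the test pair* (observations of one patient
differ only in visit time; leaving them in inflates the score). Only a
random subset of 300 pairs is scored. Ties in the search go to the
first-sampled candidate, making runs reproducible under a seed.

The search spaces are package defaults, config-overridable, documented in
`hyperparameter_space()`: penalty strength log-uniform 10^−3^…10^3^,
elastic-net mixing uniform 0–1, kNN neighbors 1–30, SVM cost/width
log-uniform, 50–500 trees of depth 2–8, GTB learning rate log-uniform
0.01–0.3, selector size 1–min(15, d).

Generalization is estimated by nested CV: the entire random search runs
inside each outer-training fold, and only outer test folds — never touched
by tuning — contribute to the generalization AUC. The expected behavior,
asserted on synthetic cohorts, is optimism: tuning AUC exceeds nested AUC
on average.

## Algorithm comparison

To ask "which classifier/selector/sampler helps", models sharing all other
components form contexts; algorithms are ranked within each context
(midranks on ties, rank 1 best) and the Friedman statistic
χ²~F~ = 12N/(k(k+1))·[ΣR̄~j~² − k(k+1)²/4] is referred to χ² with k−1 df.
The classic χ² form is used rather than the F-type refinement, matching the
comparison methodology this pipeline follows. Six families (three component
types × time-specific/longitudinal) feed one Holm–Bonferroni correction at
FWER 0.05. Significant families get a Nemenyi critical difference
CD = q~α,k~ sqrt(k(k+1)/6N), with the studentized-range quantile computed
numerically (`qtukey`), never from a hard-coded table; win-proportion
matrices (ties 0.5, M + Mᵀ = 1) summarize pairwise dominance, and
`plot_cd_diagram()` draws the standard CD diagram.

## The synthetic cohort generator

No public cohort exists for this problem, so the generator is a first-class
module that emulates the study conditions: 153 patients by default; glands
as digitized ellipsoids with semi-axes 9–17 × 9–17 × 13–24 mm (volumes
roughly 4,500–29,000 mm³); ipsilateral gland mean doses 15–35 Gy and
contralateral 5–30 Gy — conditioned 2 Gy below the ipsilateral mean,
because the treated side is by definition the higher-dose side and
unconditioned draws would contradict the planted outcome side in a quarter
of patients; lateral dose gradients of 1–2 Gy/mm at the contralateral
gland (0.5–1.5 ipsi), realized as two per-gland linear ramps blended
logistically across the midline plus 1 Gy voxel noise; ages ~N(61, 8) in
29–82, 24% female; visits on a jittered 3-month schedule to 24 months with
10% per-visit dropout.

Outcomes follow a logistic model on *standardized true features* (the
analytic contralateral volume and gradient, sex), not on hidden latent
variables, so recovery tests close the loop through the real extraction
code. The default effect template mirrors the long-term pattern the method
is designed to detect — volume protective, right–left gradient harmful,
male sex harmful — with coefficients (−2.2, +0.9, +0.4, intercept −0.6)
chosen once in a design pass so that the long-term univariate volume AUC
lands near 0.85 at n = 150; per-visit grade noise and window averaging are
what push the latent coefficient above the naive value. Grade-2+
probability per visit is logistic in the linear predictor (optionally time);
event visits split 80/20 into grades 2/3, non-event visits 55/45 into 1/0.

What the generator does *not* emulate: real parotid shapes (lobes, concave
medial surfaces), realistic treatment-plan dose falloff (two blended ramps,
not a planning system), inter-visit grade autocorrelation within patient,
baseline xerostomia, or CT texture. Passing tests therefore demonstrate
that the *pipeline* is correct and well calibrated — not that any specific
clinical AUC value transfers.

## Numerical choices and degenerate inputs

* Trilinear interpolation clamps sample points to the lattice; resampling a
  single-slice axis is an explicit error naming the axis.
* Percentiles use linear interpolation between order statistics (quantile
  type 7); constant doses give D2 = D50 = D98 exactly.
* Constant features are skipped by the screen with a warning; a vanishing
  logistic slope makes tolerance values an explicit error, not ±Inf.
* BCa clamps the bootstrap CDF at 1/(B+1) to keep z₀ finite; a fully
  degenerate bootstrap distribution yields a zero-width interval with a
  warning.
* Bernoulli group selection re-draws on the empty set rather than
  rejecting, preserving the per-group marginal probability.
* Random-search ties: first-sampled wins (deterministic under seed).
* kNN risk scores are the positive fraction among the k nearest training
  points, giving a continuous scorer without a voting tie-break.
* Stage seeds derive from the global seed by a fixed affine counter
  (`derive_seed`), keeping all stages below 2³¹ and mutually decoupled.

## Problem sizes used by the test and acceptance suites

The statistical suites run at deliberately reduced but still informative
sizes, chosen as the smallest that leave the asserted effects comfortably
outside Monte Carlo noise: FDR null calibration at 200 features × 200
replicate cohorts of n = 150; Friedman size at k = 7, N = 70, 500
replicates; permuted-label nested CV averaged over 5 permutations of a
100-patient cohort; planted-effect recovery as the median over 20
simulated cohorts of n = 150 with nested CV on the median cohort (outer 15
splits, inner 15, 6 search iterations — the point where the estimate
stabilizes under further budget increases); optimism over 20 cohorts of
n = 60 at reduced budgets. The full 1,960-model sweep at 300-iteration budgets is
cluster-scale by design and is exposed through configuration rather than
run in tests.

## Known limitations

* DICOM-RT objects are not parsed directly; volumes enter as NIfTI files
  or in-memory arrays, and structure sets as contour stacks already read
  from the source format.
* The coarea surface-area estimator is biased low on shapes with sharp
  edges; shape features are intended for smooth organ masks.
* The modified LPOCV AUC estimator is unbiased for the pooled pairwise
  ranking probability but its BCa interval treats pairs as independent,
  which understates width when few patients dominate many pairs.
* Nested CV with small outer budgets has visibly wide intervals; the
  defaults trade compute for variance and should be raised for real
  studies.
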
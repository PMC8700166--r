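---
title: "Estimating GFR from serum markers: models, metrics and the development pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating GFR from serum markers: models, metrics and the development pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfrtools)
```

## The estimation problem

The glomerular filtration rate is the standard measure of kidney function.
Measuring it directly requires an exogenous tracer clearance (iothalamate,
iohexol, inulin or ⁵¹Cr-EDTA), normalized to 1.73 m² body surface area via
the Dubois formula BSA = 0.007184·height^0.725·weight^0.425. Routine care
instead *estimates* GFR from endogenous serum markers. This package
implements one family of such estimators — a piecewise power law combining
cystatin C, creatinine, valine and myo-inositol with age and sex — next to
the established creatinine/cystatin C spline equations (CKD-EPI 2009,
CKD-EPI cystatin 2012, CKD-EPI creatinine–cystatin 2012, EKFC), and the
apparatus used to develop, select and validate estimators of this kind.

All equations are evaluated unrounded; any rounding happens only in
reports. Units are fixed by the coefficient tables: creatinine, valine and
myo-inositol in µmol/L, cystatin C in mg/L, GFR in mL/min/1.73 m².
Creatinine supplied in mg/dL is converted with the molar-mass factor
88.42. Benchmark equations published in mg/dL convert internally; the
canonical in-memory unit is µmol/L. The race coefficients of the CKD-EPI
equations are applied exactly as published and default to non-black when
the flag is absent. Estimates are not capped at either end.

Branching of the piecewise equation: the cystatin C cutoffs are 1.02 mg/L
(female) and 1.22 mg/L (male), and a concentration exactly at the cutoff
takes the at-or-above branch, matching the strict-below/at-or-above
partition of the published table. Because the printed coefficients are
rounded, the two branches do not meet exactly at the cutoff; the relative
gap is about 0.04% and is asserted to stay below 0.5% by the test suite.
For the EKFC rescaling constant Q we use the published adult constants
(0.70/0.90 mg/dL) from age 25 up and the published age polynomial for ln Q
below 25; cohorts here contain adults (≥ 18), so the polynomial covers only
the 18–25 sliver.

## Validation metrics

Differences are defined as eGFR − mGFR, so underestimation of measured GFR
gives negative bias. The summary metrics are the median signed difference
(bias), the interquartile range of the differences (precision), the mean
absolute difference (MAE) and the root-mean-square difference of log1p
values (RMSLE). Quantiles use type-7 linear interpolation — the default of
this statistical environment — wherever quartiles or percentile intervals
are formed. Accuracy is reported as 1-Px, the percentage of samples whose
estimate deviates from mGFR by more than x% of mGFR, at x = 15, 20, 30; a
deviation exactly at the boundary counts as *within*, reading "within x%"
inclusively. The regression-error-characteristic curve is Px as a function
of x and is non-decreasing by construction.

Confidence intervals use the percentile bootstrap: whole (eGFR, mGFR)
pairs are resampled with replacement, 1000 replicates by default, and the
2.5th/97.5th percentiles of the replicate statistics are reported.
Replicates on which a statistic is undefined (e.g. an empty subgroup) are
skipped and counted; more than 10% skipped replicates aborts the
computation rather than silently reporting a biased interval. All
resampling is seeded and bit-reproducible.

Paired equation comparisons use the two-sided Wilcoxon signed-rank test on
per-sample differences of signed errors (bias) and of absolute errors
(MAE); the signed-error variant is the default reading of "bias", with the
absolute variant available through the same function. Accuracy differences
use McNemar's test on the paired within/outside indicators with the
classical continuity correction ((|b−c|−1)²/(b+c)); an exact binomial
variant is available behind a flag. IQR differences use a two-sided
bootstrap test (twice the minority fraction of replicate differences
across zero). Identical inputs yield p = 1 by convention, logged rather
than silent. Benjamini–Hochberg adjustment is applied across the set of
pairwise comparisons within each metric family.

## Staging and reclassification

KDIGO stages partition (0, ∞) by half-open intervals: G1 [90, ∞), G2
[60, 90), G3a [45, 60), G3b [30, 45), G4 [15, 30), G5 (0, 15). Staging is
applied to unrounded GFR values. For reclassification of one equation
against a comparator relative to the mGFR-based stage, discordant samples
(the two equations disagree on stage) split into *correct* (new equation
matches the mGFR stage), *incorrect* (comparator matches) and *both wrong*;
the last group is reported separately rather than folded into either
count. Strata are defined by the mGFR-derived stage: published
reclassification tables carry an "estimated GFR range" header, but their
per-stratum sample counts match the measured-GFR stage distribution, so
the measured stage is the stratification variable here.

Two NRI variants are reported. The primary, printed-style NRI is the
difference of the one-decimal-rounded (half-away-from-zero) correct and
incorrect percentages; this convention reproduces every NRI of the
published reclassification table, including the stratum where the exact
ratio rounds differently (25.2 − 10.3 = 14.9 vs. 15.0). The exact NRI,
100·(correct − incorrect)/n, is always reported alongside.

## The development pipeline

Candidate equations are linear models over a pool of ten serum parameters
(nine NMR metabolites plus cystatin C), each usable raw or natural-log
transformed, with mGFR or log mGFR as response. Four constraints bound the
search: two to five features; at most one interaction term (the product of
two transformed features of *distinct* parameters — squares are excluded by
default because parameters, not features, are the unit of identity, though
a toggle enables them for sensitivity analysis); an interaction must
involve at least one parameter already present as a main effect; and no
parameter may appear with two different transforms anywhere in a model,
counting main effects and interaction components jointly.

Under these constraints the closed-form count for the ten-parameter pool
is 487,008 formulas (12,564 main-effect models and 230,940 with an
interaction, per response, times two responses). The historically reported
figure for this search is 487,408 — 0.08% higher; no interpretation of the
constraints we tested (self-interactions, extra response, alternative
interaction-transform conventions) reproduces that figure exactly, so the
gap is documented here rather than absorbed by tuning. Both the
enumerator and the closed form are exposed, agree with each other and with
an independent brute-force count for small pools under every constraint
toggle, and the enumerator can stream formulas through a callback in
constant memory.

Fitting is ordinary least squares on the design implied by the formula.
For the log response, predictions are back-transformed by plain
exponentiation without smearing correction — the final equation is a plain
product form, which a smearing factor would break. Performance indicators
(MAE, P15/P20/P30) are always computed on the GFR scale. Rank-deficient
designs raise an explicit collinearity error. Cross-validation is
five-times-repeated five-fold with seeded shuffled fold assignment,
unstratified by default (a stratification column can be supplied); the
stability indicator is the coefficient of variation of the 25 fold MAEs.

Deselection is a configurable ordered rule pipeline, not a hard-coded
filter sequence: the historical 14-step pre-filtering and 8-step selection
used expert-chosen thresholds on data that are not available, so the
package ships the rule *classes* (KPI thresholds on MAE/P30, CV-stability,
upper-range reach — the fraction of samples with mGFR ≥ 90 predicted ≥ 90,
heteroscedasticity — the absolute Spearman correlation of |residual| with
fitted values, and redundancy pruning that keeps the MAE/P20 Pareto front
within groups sharing a minimum number of features) with illustrative
default thresholds in a YAML config. Every rule application is audited
with its removal count, and adding a rule can never enlarge the survivor
set.

Model engineering refits a surviving candidate jointly on the log-GFR
scale with branch-specific intercept and pivot-marker coefficient (sex ×
cutoff side, four branches; or cutoff side only) while all other
coefficients are shared across branches. The joint fit — rather than
per-stratum fits with post-hoc averaging — is what the published table's
identical shared coefficients across branch rows imply. Age can be added
as a shared linear term in the same refit. A branch with fewer samples
than coefficients aborts with the branch named. Competing candidates are
compared with the classical Vuong statistic: the mean pointwise
log-likelihood difference over its sample standard deviation, √n-scaled,
against the standard normal, with Gaussian likelihoods formed from each
model's maximum-likelihood residual variance; identical likelihood vectors
are reported as non-significant with a warning rather than a division by
zero.

## The synthetic cohort generator

Because no patient-level data ship with the package, a seeded generator
stands in. It emulates the marginals of the target population — mGFR
truncated normal 67 ± 28 on (3, 183) mL/min/1.73 m², age 56 ± 14 on
(18, 88) years, 55% male, BMI 30 ± 6 with height 170 ± 10 cm and weight
derived from BMI — and links each marker to the latent mGFR through a
lognormal: exp(intercept + slope·ln mGFR + sex-shift·male + noise). Slopes
are sign-constrained (creatinine, cystatin C, myo-inositol fall with GFR;
valine rises), and the default intercepts place typical healthy values at
mGFR ≈ 90 (creatinine ≈ 80 µmol/L male, cystatin C ≈ 0.9 mg/L,
myo-inositol ≈ 30 µmol/L, valine ≈ 240 µmol/L). These link coefficients
are deliberate synthetic choices, documented as such, and are not
estimates of any real joint distribution. Truncation is by rejection
sampling with a resample cap; exceeding the cap is an error, not a silent
clamp. Liver disease and clinical indication are inert labels carried for
stratified partitioning, which allocates rows within each stratum cell by
largest-remainder rounding (per-cell deviation at most one sample) after a
seeded shuffle.

What passing tests on generated cohorts do show: the generator, the
fitter, the piecewise engineering and the equation evaluator are mutually
consistent — simulating mGFR from the published equation structure with
log-scale noise σ = 0.1 and refitting recovers every exponent, base and
branch coefficient within three standard errors at n = 2000. What they do
not show: anything about the comparative clinical performance of the
equations. The generator's simplified marker links do not reproduce the
published validation tables, their subgroup analyses or figure-level
results, and no attempt is made to tune them in that direction; on
synthetic cohorts the benchmark spline equations can outperform the
metabolite equation, which is an artefact of the generator, not a clinical
finding.

## Numerical choices and problem sizes

Quantile type 7 throughout; half-away-from-zero rounding for printed-style
percentages; accuracy boundaries inclusive; bootstrap 1000 replicates with
type-7 percentile endpoints; Wilcoxon with normal approximation
(`exact = FALSE`) for stable behaviour on tied differences; the Vuong
denominator uses the sample standard deviation. Degenerate inputs are
handled by convention and logged: all-zero paired differences give p = 1,
constant bootstrap statistics give zero-width intervals, empty strata
report missing NRI. The test-suite problem sizes — 1000 random inputs for
equation-oracle equivalence, pools of up to five parameters for
enumeration cross-checks (the ten-parameter count is verified in closed
form), n = 2000 for coefficient recovery, 200 cohorts of n = 100 for
bootstrap-coverage calibration — were chosen to make each statistical
assertion sharp at desk scale while the whole suite stays fast.

## Limitations

The package evaluates and develops estimating equations; it does not model
outcomes, albuminuria staging or continuous NRI variants, and it does not
touch marker measurement (NMR acquisition, assay calibration). The
shipped deselection thresholds are illustrative defaults, not the
historical expert choices. The 400-formula gap between the closed-form
candidate count and the historically reported figure remains unexplained
by any constraint interpretation we tested. Pediatric equation variants
and the 2021 race-free CKD-EPI refit are out of scope; ages under 18 are
accepted with a warning.
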
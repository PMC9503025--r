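---
title: "Methods: the adjusted Tokuhashi score and its development pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the adjusted Tokuhashi score and its development pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atscore)
```

## The clinical problem and the score

For patients undergoing surgery for spinal metastases, expected survival
drives the choice between aggressive excision (worthwhile only if the
patient lives long enough to benefit) and palliative decompression. The
revised Tokuhashi score (RTS) sums six rubric domains — general condition
(Karnofsky bands), extraspinal metastatic foci, number of vertebral-body
metastases, visceral metastases, primary tumour site, and palsy (Frankel
bands) — into a 0–15 total, higher being better. Scores of 8 or less
define the poor-prognosis group (g1), 9–11 the intermediate group (g2),
12 or more the favourable group (g3). In contemporary cohorts the rubric
misclassifies mostly in one direction: g1 patients who in fact survive
past the six-month landmark.

The adjusted score targets exactly that failure mode by adding two
factors available in any chart review:

$$\mathrm{ATS} = \mathrm{RTS} + a \cdot \mathrm{Target} + b \cdot Z_{\mathrm{BMI}},$$

with `Target` ∈ {0, 1} the use of molecularly targeted systemic therapy
and $Z_{\mathrm{BMI}}$ the body-mass index standardized against the
general-population mean and SD for the patient's sex and age band (a
proxy for nutritional status and cachexia). The published weights are
$a = 4$, $b = 1$; survival beyond six months is predicted when ATS
exceeds a cutoff, 7.5 by default. A two-step rule first waives every
RTS ≥ 9 patient through as a favourable prediction — the rubric is
already accurate there — and re-examines only g1 with the adjusted score.

## Scoring conventions

* **Strict threshold.** `classify_6mo()` predicts the favourable class
  only when the score *strictly* exceeds the cutoff. With half-integer
  cutoffs such as 7.5 the strict/non-strict choice is immaterial for
  integer-valued scores; it matters only for the alternative integer
  preset (cutoff 8, mirroring the rubric's own "total > 8" boundary),
  and the strict rule keeps that preset consistent with "RTS ≥ 9 is
  favourable".
* **Z-BMI is unbounded**, so ATS may leave [0, 15]. No clamping is
  applied: the score is used only through rank-based statistics and a
  threshold rule, both insensitive to range.
* **BMI is the authoritative field.** Height and weight are optional and
  only checked for consistency (|BMI − kg/m²| ≤ 0.1) when both are
  present, since the underlying measurement protocols record BMI.
* **Reference tables are data, not code.** Age bands, means and SDs are
  read from a CSV; validation requires positive SDs and, per sex,
  disjoint closed integer bands jointly covering ages 18–120. The
  shipped `bmi_reference_synthetic.csv` is an illustrative synthetic
  table (bands 18–44 / 45–64 / 65+), not a national reference.

## Evaluation machinery

* **AUC** is the tie-corrected concordance probability, computed by
  midranks; this equals a brute-force scan over all positive–negative
  pairs with ties scored ½ (the test suite checks the equality on random
  instances up to n = 200). Curve thresholds are midpoints between
  adjacent distinct scores plus ±∞ sentinels.
* **Paired AUC comparison** uses the DeLong placement-value estimator of
  the variance of the AUC difference, with a two-sided z-test. The
  estimator is algebraically identical to the grouped delete-one
  jackknife, which the test suite verifies to 1e-9 against a jackknife
  oracle that recomputes both AUCs from scratch at every deletion; a
  10⁴-draw permutation test provides a second, distribution-free check.
  When the two score vectors are identical the difference and its
  variance are both zero; the test then reports z = 0, p = 1.
* **Cutoff selection** maximizes Youden's J over the midpoint candidates;
  ties break toward the *smallest* cutoff, which maximizes sensitivity —
  the natural choice for a screening rule whose costly error is sending a
  survivor to palliative-only care. With a single distinct score there
  are no midpoints; the score itself is returned with J = 0.
* **Positive class = alive at six months**, so higher scores are
  favourable; sensitivity is P(score > cutoff | alive). Subjects censored
  before the landmark have indeterminate status: they are excluded from
  classification metrics and the logistic models but retained (as
  censored observations) in Kaplan–Meier curves.
* **Kaplan–Meier and log-rank** computations delegate to the `survival`
  package (`survfit`, `survdiff`) behind the package's interfaces;
  survival lookups are right-continuous step functions. **Logistic
  models** delegate to `glm` (IRLS, at most 25 iterations, tolerance
  1e-8) with Wald odds ratios and 95% CIs on the log-odds scale —
  consistent with how such prognostic-factor tables are conventionally
  reported — plus explicit separation detection (boundary fitted
  probabilities or |log-odds| > 15 flag the fit as non-converged rather
  than silently returning divergent estimates).
* **Group summaries** use one-way ANOVA for continuous variables and the
  chi-square test for categorical ones, with the Yates continuity
  correction applied to 2×2 tables whenever an expected count is below 5.

## The weight search and pipeline

`auc_grid()` evaluates the 6-month AUC of RTS + a·Target + b·Z-BMI over
an integer lattice (default a, b ∈ 1…10; 0 and fractional steps are
accepted) within a search population defaulting to group 1 — the
population where the rubric fails and where the published grid was
computed. `select_best_weights()` takes the argmax, breaking ties toward
smaller a then smaller b (prefer the least perturbation of the
established rubric) and reporting the tie count. The full pipeline
censors at the horizon, searches on the reference cohort, freezes the
selected weights, picks the Youden cutoff on the reference cohort, and
only then touches the validation cohort — weights and cutoff are never
refit downstream. Both the cohort-wide and the group-1-restricted AUC
comparisons are always reported, since the headline discrimination
comparison is conventionally cohort-wide while the search objective is
group-1-restricted.

## What the synthetic generator emulates

Patient-level data for this problem are not publicly deposited, so the
package ships a generator (`generate_cohort()`) whose defaults encode the
documented cohort structure: n = 171, 60% male, age 56 ± 9.9 years
truncated to 19–89, BMI near 23 kg/m² (sex-specific normals, SD 3.2),
prognostic-group mix 116/42/13, 61% target-therapy use, and six-month
survival odds ratios of 1.41 per RTS point, 7.08 for target therapy and
1.89 per Z-BMI unit, with 42.2% baseline six-month survival in group 1
and 3% loss to follow-up.

Key constructions, and why:

* **Rubric draws** condition on the drawn prognostic group by rejection
  sampling over per-group categorical laws (bounded at 1000 rounds); the
  primary-site law is lung-heavy in g1 and breast/prostate-heavy in g3,
  matching the documented site mix. The exact joint law of the six
  domains is not identifiable from group-level summaries; these weights
  are a modeling choice, and only the group bands and site ordering
  should be regarded as calibrated.
* **Intercept calibration.** The true survival probability is logistic
  with slopes log(OR). The intercept is solved by `uniroot` (tolerance
  1e-10) so that the *realized mean* of P(survive 6 mo) over group-1
  patients equals the 0.422 target — calibrating the mean linear
  predictor instead would be biased by Jensen's inequality at the
  realized spread of the predictor.
* **Survival times** are exponential with rate −log(p)/6, which matches
  P(T ≥ 6) = p exactly. The landmark analyses depend on the survival law
  only through that tail probability, so any law with the right
  six-month tail would do; the exponential is the simplest. Consequently
  the *shape* of the generated Kaplan–Meier curves (constant hazard) is
  not calibrated to real cohorts, and nothing downstream should be read
  as validating it.
* **Loss to follow-up** occurs only among patients surviving past six
  months (as documented for the emulated cohort), with a uniform censor
  time on (6, min(T, horizon)). A corollary worth knowing: generated
  cohorts contain *no* indeterminate six-month labels, mirroring a study
  that excluded such patients up front. The indeterminate-handling code
  paths are therefore exercised by constructed fixtures, not by the
  generator.
* **Determinism.** All randomness flows from the single configured seed.

Passing tests on these cohorts show that the pipeline recovers known
structure (effect-size asymmetry, group survival ordering, calibrated
baselines) from data that satisfy its assumptions; they cannot show
robustness to the messiness of real registries (informative censoring,
site-specific therapy coupling, non-proportional hazards, measurement
error in BMI).

## Problem sizes and test design

The suite verifies the statistical kernels against independent oracles
at small n (brute-force AUC to n = 200, jackknife at n = 12, hand
product-limit and O−E tables at n ≤ 6, closed-form 2×2 odds ratio) and
the generator's calibration at larger n chosen to make Monte-Carlo error
negligible relative to the tolerance: 20 000 patients for the 0.422 ±
0.02 group-1 survival target, 50 seeds of ~2000-patient group-1
subcohorts for CI coverage (checked per predictor against the ≥ 90%
bar — the statistically coherent reading, since joint coverage of three
nominal-95% intervals is expected to fall below 90%), and 100 seeds of
the 171/57 development/validation pipeline for the weight-asymmetry and
AUC-superiority properties.

## Known limitations

* The rubric's primary-site tiers are fixed to the published six-tier
  list; re-weighting the original six domains is deliberately out of
  scope — the method's premise is to augment, not refit, the established
  score.
* The 12-month landmark is not an optimization target (the adjusted
  score was developed for the 6-month decision point, where the rubric
  fails); `landmark_labels()` accepts any landmark for descriptive use.
* Single-cohort weight selection is noisy: on 171-patient reference
  cohorts the selected (a, b) varies substantially by seed even when the
  generating effect sizes are fixed, and only the a > b asymmetry is a
  stable recovery target. Users applying the shipped default weights
  (4, 1) to new populations should treat them as published constants to
  be externally validated, not as estimates this package certifies.
* No competing-risks, Cox, or time-dependent-covariate modeling; the
  evaluation battery is the landmark-classification and
  univariate-survival toolkit appropriate to the score's design.
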
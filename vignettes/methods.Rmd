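---
title: "Methods: design-based phthalate–retinopathy association analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: design-based phthalate-retinopathy association analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phthalret)
```

This vignette is the package's account of its statistical machinery: the
models and procedures, the assumptions they lean on, the parameters worth
tuning, what the synthetic cohort generator does and does not emulate, and
the numerical and design choices made where more than one defensible option
existed.

## 1. Cohort definition

`apply_inclusion_criteria()` defines the analyzable diabetic cohort. A
subject qualifies either by questionnaire — a "yes" to self-reported
diabetes, current insulin use, or diabetic pills, with refused/don't-know/
missing answers never qualifying — or, failing that, by a glycated
hemoglobin value of at least 6.5% (the standard laboratory threshold for
undiagnosed diabetes). Age at screening must be at least 20 years, and where
an age at diagnosis exists it must also be at least 20, restricting the
cohort to adult-onset disease. Subjects who qualify only through HbA1c have
no diagnosis age and pass that filter vacuously; this is the one point where
the rule is genuinely ambiguous (one could instead exclude them), and we
chose the permissive reading because the HbA1c route exists precisely to
capture people never given a diagnosis. The function records a selection-flow
count vector so the analyst can audit each attrition step.

## 2. Exposure transformation

Three steps map raw assay readings to the analysis scale:

* **LOD substitution.** Readings below the limit of detection are replaced
  by LOD/2 (`substitute_lod()`), the conventional single-value fill-in for
  left-censored urinary biomarkers. No likelihood-based or multiple-
  imputation treatment of censoring is attempted; with the rank transform
  downstream, all censored values in a metabolite collapse to one tie group,
  which average ranks handle.
* **Dilution correction.** `dilution_correct()` returns
  log(concentration/creatinine). The ratio deliberately mixes units (ng/mL
  over mg/dL): any consistent unit change multiplies the ratio by a
  constant, shifts the log by a constant, and is annihilated by the rank
  transform. The natural log is used; the base is likewise irrelevant.
* **Inverse normal transformation.** `inverse_normal()` ranks the values
  (average ranks for ties), forms empirical CDF points, and applies the
  standard-normal quantile function. The default CDF convention is
  rank/(n+1), which keeps all quantiles finite; Blom
  ((rank − 3/8)/(n + 1/4)) and (rank − 1/2)/n offsets are available because
  statistical packages differ here and the choice is not derivable from a
  verbal description of the procedure. The differences are far inside the
  sampling noise of any analysis in this package.

The composition is invariant under strictly increasing transformations of
the inputs, so the tests assert unit-invariance exactly. One consequence
worth stating: the output is *monotone* in the input (rank correlation 1),
but its Pearson correlation with the input ranks is the uniform-versus-
normal-quantile constant ≈ 0.977, not 1.

Ranking is done once over the pooled analysis dataset, not within survey
cycle; with a single combined table there is no principled way to recover
cycle-wise ranks, and per-SD effect estimates are insensitive to the
distinction.

## 3. Design-based estimation

All inference uses the with-replacement first-stage approximation standard
for public-release survey data: strata are fixed, PSUs within a stratum are
the units of variation, and there is no finite-population correction.

* `design_proportion()` / `design_mean()` compute the Horvitz–Thompson ratio
  estimate Σwy/Σw with a Taylor-linearized SE from the between-PSU
  covariance of the linearized residuals w(y − θ̂)/Σw.
* `fit_weighted_logistic()` maximizes the sampling-weighted log-likelihood
  by iteratively reweighted least squares and wraps the usual sandwich:
  bread = inverse weighted information, meat = stratified between-PSU
  covariance of PSU totals of the weighted scores w(y − p)x.
* Degrees of freedom are `#PSUs − #strata`, and CIs/p-values use the t
  distribution on that df — the convention of the survey software the
  field predominantly uses. With the default 15-strata × 2-PSU design this
  gives 15 df, so CIs are noticeably wider than normal-theory ones; the
  coverage simulation in the test suite confirms near-nominal behavior.

Numerical choices: convergence is declared when the maximum absolute
coefficient change drops below 1e-10 (at most 100 iterations); each Newton
step is halved until the weighted log-likelihood stops decreasing, which
makes warm starts (used heavily by the Monte Carlo module) exactly as safe
as cold starts; a coefficient norm exceeding 1e4 aborts with a separation
diagnostic; constant predictors and singular information matrices are hard
errors. Strata with a single PSU are an error by default, with an explicit
`single_psu = "center"` escape hatch (center the lone PSU total at the grand
mean) because subsetting real survey data produces them routinely.

`pool_cycle_weights()` divides weights by the number of pooled survey
cycles. Every statistic this package reports is a ratio estimator and is
invariant to that divisor, so the default is 1 (weights used as given); the
option exists for users who want population totals on the right scale when
combining cycles.

## 4. Covariate coding

`encode_covariates()` implements a fixed integer coding for the confounders
(obesity 2/1/0, activity 2/1/0, HbA1c strata 2/1/0, lipid strata,
hypertension, diabetes-duration bands 4–0, calorie quartiles 0–3,
demographics), with *every* missing or unknown value coded 0. Coding missing
to a "reference-ish" level rather than dropping rows keeps the full cohort
in every multivariable model — the trade-off is a mild attenuation of that
covariate's coefficient, accepted deliberately in exchange for a constant
analysis population across the nested sequence. The estimators therefore
require complete numeric input and refuse missing values.

## 5. Association scan and nested models

`univariate_scan()` fits one design-based logistic model per metabolite and
applies a Bonferroni correction with the family size fixed at the number of
metabolites scanned (12), regardless of individual fit failures — the
correction describes the scan that was attempted, not the subset that
converged. `nested_models()` fits a fixed cumulative sequence: the other 11
metabolites first, then one covariate block per model up to the full
16-model specification. The sequence is configuration, not data-driven
selection; "stepwise" here means a pre-declared ordering of adjustment sets,
so results are reproducible and the exposure coefficient can be tracked
across models.

`molar_sum_dnop()` converts the two di-n-octyl-phthalate derivatives to a
molar sum (MOP/278.34 + MCPP/252.22, ng/mL over g/mol ≡ µmol/L). The
molecular weights are computed from the molecular formulas (C₁₆H₂₂O₄ and
C₁₂H₁₂O₆) with standard atomic weights and stored as named constants.

## 6. Outcome validation and the misclassification Monte Carlo

`crosstab()` tabulates the 4-level imaging grade against self-report and
collapses to a 2×2 with *positive imaging defined as moderate/severe NPR or
PR* — mild nonproliferative changes are counted as imaging-negative, because
that is the clinically meaningful threshold for the misclassification
argument. `cohens_kappa()` reports the chance-corrected agreement with a
large-sample SE under independence; both a raw count-based and a
design-weighted variant (weight sums in place of counts) are always
computed, since with unequal weights they answer different questions and
neither is redundant. With equal weights they coincide exactly (asserted in
tests).

`extract_misclass_rates()` conditions on the self-report margin: the
false-positive rate is the share of self-reported cases without positive
imaging; the false-negative rate is the share of self-reported non-cases
with positive imaging. These are the rates a reshuffling simulation needs.

`run_misclass_mc()` flips each observed case to control with the
false-positive rate and each observed control to case with the
false-negative rate, independently per subject and per replicate, refits the
full model, and records the exposure coefficient. Flips are applied to the
*observed* outcome, not a latent truth — the point of the exercise is "how
fragile is the estimate we actually obtained under plausible outcome
error", not a formal deconvolution. Independent Bernoulli flips are used
rather than count-preserving rebalancing; the flip rule is small and
exposed, so a user preferring margin-preserving reshuffles can supply their
own outcome vectors. The summary CI is exp(mean ± 1.96·SD) of the replicate
coefficients (a percentile CI is also emitted); with zero rates every
replicate equals the base fit and the SD is exactly 0. More than 5%
replicate fit failures abort the analysis. Nondifferential outcome
misclassification attenuates effects toward the null, and the test suite
checks that monotonicity at two rate levels.

## 7. Dose-response

`bin_by_sd()` cuts the transformed exposure at −1, 0, +1 SD (left-open,
right-closed except the first bin). Because the transformed scores are
already N(0,1) by construction, weighted and unweighted means/SDs coincide
up to rank-approximation error and the cut points are taken at the nominal
values. `cochran_armitage()` implements the signed trend statistic with
integer scores 1..k (affine-invariant; order reversal flips the sign only).
The trend test runs on unweighted counts while the per-bin prevalences are
design-corrected; this mismatch is deliberate — the classical Armitage test
has no weighted analogue with the same null distribution — and a
design-consistent companion (survey-weighted logistic fit on the bin index)
is reported alongside. Per-bin prevalence SEs use the single-PSU centering
fallback because binning can isolate PSUs.

## 8. The synthetic cohort generator

`generator_config()` / `generate_cohort()` produce cohorts with known ground
truth. What it emulates:

* a stratified design (default 15 strata × 2 PSUs, the df scale of a
  multi-cycle national survey), every cell populated with at least two
  subjects, log-normal unequal weights (meanlog log 20000, sdlog 0.7);
* 12 correlated log-normal metabolite concentrations. Means target observed
  arithmetic means in diabetic adults; spreads default to sdlog 1 except
  MOP, whose sdlog 0.371 is calibrated so that ~73% of readings exceed its
  0.84 ng/mL LOD at an arithmetic mean of 1.13 ng/mL. The default
  correlation is exchangeable 0.3 with the three DEHP oxidation products
  (MEHP, MEHHP, MEOHP) at 0.8, mimicking within-parent clustering;
* LOD censoring: the stored concentration is the LOD itself with a
  `below_lod_*` flag; uncensored draws are kept in an attribute for oracle
  checks, and the analysis chain only ever sees the censored data;
* urinary creatinine, log-normal around 110 mg/dL (sdlog 0.6);
* Table-1-style coded confounders drawn at realistic category frequencies;
* a logistic outcome model **on the analysis scale**: the generator runs the
  package's own LOD/2 → dilution → inverse-normal chain and draws the true
  outcome from `logit p = intercept + Σ β_m z_m (+ γ'c)`. Defining truth on
  the transformed scale makes `true_log_or` the exact estimand of the
  fitted models, so parameter-recovery tests are clean rather than
  attenuation-confounded. The default intercept gives ~13.9% prevalence
  under null effects;
* self-report misclassification calibrated **on the self-report margin**:
  the configured rates are P(no true disease | self-reported case) = 0.112
  and P(true disease | self-reported non-case) = 0.0492 — the quantities a
  validation cross-tab measures. The generator inverts them through the
  realized truth prevalence π via s = (π − fn)/(1 − fp − fn),
  P(report|case) = (1−fp)s/π, P(report|control) = fp·s/(1−π), so
  `extract_misclass_rates()` round-trips the configuration (a property
  test). Zero rates reproduce the truth exactly. Rates incompatible with
  the realized prevalence raise an informative error;
* an imaging substudy (default fraction 285/1004) whose default grade
  multinomials make imaging positivity coincide with the latent truth
  (cases → moderate/severe NPR 0.8 / PR 0.2; controls → none 0.75 / mild
  0.25, matching observed subsample grade frequencies). This is a modeling
  convenience required for exact round-trips, not a claim that imaging is
  error-free; the multinomials are configurable;
* eligibility fields with a small configurable fraction of ineligible
  records so the selection flow is exercised.

One master seed drives everything through derived per-component substreams,
so a stage can be replayed in isolation and cohorts are byte-identical
across runs.

What it does **not** emulate: real multistage selection probabilities or
weight-raking, informative sampling (weights are independent of outcome and
exposure), cycle-to-cycle assay drift, within-person repeated measures,
covariate–exposure confounding unless explicitly configured via
`covariate_log_or`, and differential (exposure-dependent) outcome
misclassification. Passing tests therefore demonstrate correctness of the
estimators and the internal consistency of the pipeline under a known
data-generating law — not robustness to the many ways real survey data
violate it.

## 9. Test and simulation scale

The test suite's simulation sizes are chosen to give stable Monte Carlo
verdicts at interactive runtimes: 200 replicates at n = 1000 for effect
recovery and CI coverage (three MC standard errors as the bias budget),
500 replicates at n = 2000 for misclassification attenuation, 200 null
cohorts at n = 400 for family-wise error and trend-p calibration, and
300 replicates at n = 400 for null CI coverage. The acceptance script's
synthetic run uses n = 2000 with 500 Monte Carlo replicates.

## 10. Known limitations

* LOD/2 substitution is a crude censoring treatment; with heavy censoring
  the bottom tie group dominates a metabolite's transformed scale.
* The kappa SE is the large-sample formula under independence, appropriate
  for testing κ = 0 but not for CIs around large κ.
* The design-weighted kappa reuses the unweighted n in its SE; it is
  reported as a descriptive companion, not an inferential quantity.
* The misclassification MC treats the validation-derived rates as known
  constants; uncertainty in the rates themselves is not propagated.
* Nested-model sequences are fixed by configuration; no data-driven
  selection, interactions, or penalization.
* Single-PSU centering (`single_psu = "center"`) biases variances downward
  relative to a fully specified design; it is an escape hatch, not a
  recommendation.
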
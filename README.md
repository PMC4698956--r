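# phthalret

Design-based association analysis of urinary phthalate metabolites with
self-reported diabetic eye affliction/retinopathy.

## The problem

Phthalates are ubiquitous plasticizers whose urinary metabolites (MBP, MCP,
MEP, MEHP, MNP, MOP, MBzP, MNM, MCPP, MEHHP, MEOHP, MiBP) serve as exposure
biomarkers. Epidemiological evidence links phthalate exposure to type 2
diabetes; a natural follow-on question is whether exposure is also associated
with diabetic complications such as retinopathy. Testing this in a national
health survey such as NHANES raises four methodological problems at once:

1. **Exposure scale.** Urinary concentrations are heavily right-skewed,
   censored at an assay limit of detection (LOD), and confounded by urine
   dilution. The pipeline substitutes LOD/2 for censored readings, corrects
   for dilution as the log ratio of metabolite to urinary creatinine, and
   maps each corrected variable to an exactly standard-normal score with a
   rank-based inverse normal transformation, so every metabolite is analyzed
   on a common per-SD scale.
2. **Complex sampling.** NHANES uses a stratified multistage design with
   unequal weights. All estimates here are design-based: Horvitz–Thompson
   ratio means/proportions, and pseudo-maximum-likelihood logistic regression
   whose covariance is the Taylor-linearized sandwich built from
   between-PSU variation of weighted score totals within strata, with t
   inference on `#PSUs − #strata` degrees of freedom.
3. **Outcome error.** The outcome is a self-reported answer ("has a doctor
   told you diabetes has affected your eyes…"), validated against
   fundus-imaging retinopathy grades (none / mild NPR / moderate-severe NPR /
   PR) available in a subsample. The pipeline computes the cross-tabulation,
   percent agreement and Cohen's kappa, extracts false-positive and
   false-negative rates, and propagates them through a Monte Carlo
   sensitivity analysis: reshuffle cases/controls at those rates, refit the
   full multivariable model per replicate, and summarize the coefficient
   distribution.
4. **Multiplicity and dose-response.** The 12-metabolite univariate scan is
   Bonferroni-corrected (family size fixed at 12); a cumulative sequence of
   16 multivariable models probes confounding; and a Cochran–Armitage trend
   test across standard-deviate exposure bins checks dose-response.

Everything is exercised end-to-end on a synthetic NHANES-like cohort
generator with known ground truth (configurable survey design, correlated
log-normal exposures with LOD censoring, logistic outcome model on the
transformed scale, calibrated self-report misclassification against an
imaging gold standard), so every stage is testable without access to survey
microdata.

## The core model

For subject *i* with weight *w<sub>i</sub>*, exposure score
*z<sub>i</sub>* = Φ⁻¹(rank(log(x<sub>i</sub>/creatinine<sub>i</sub>))/(n+1))
and covariates **c**<sub>i</sub>, the pseudo-MLE solves

&nbsp;&nbsp;Σ<sub>i</sub> w<sub>i</sub> (y<sub>i</sub> − expit(α + β z<sub>i</sub> + **γ**′**c**<sub>i</sub>)) (1, z<sub>i</sub>, **c**<sub>i</sub>)′ = 0

with covariance **B** **M** **B**, where **B** is the inverse weighted
information and **M** = Σ<sub>h</sub> n<sub>h</sub>/(n<sub>h</sub>−1)
Σ<sub>j</sub> (**z**<sub>hj</sub> − **z̄**<sub>h</sub>)(**z**<sub>hj</sub> −
**z̄**<sub>h</sub>)′ over PSU score totals **z**<sub>hj</sub> within strata.
exp(β) is the odds ratio per 1 SD of transformed exposure.

## Worked example

```r
library(phthalret)

cfg <- generator_config(
  n_subjects = 3000,
  true_log_or = setNames(c(rep(0, 5), log(1.6), rep(0, 6)),
                         default_metabolites()),  # only MOP has an effect
  seed = 2026)
cohort <- apply_inclusion_criteria(generate_cohort(cfg))
cohort <- transform_exposures(cohort, default_metabolites(), default_lods())
design <- survey_design(cohort$stratum_label, cohort$psu_label,
                        cohort$sampling_weight)

univariate_scan(cohort, design)[c(4, 6), ]
#>   metabolite  coef     se   or ci_lower ci_upper  p_value p_bonferroni
#> 4       MEHP 0.228 0.0864 1.26     1.05     1.51 1.85e-02     0.221526
#> 6        MOP 0.471 0.0861 1.60     1.33     1.92 6.49e-05     0.000779
```

Only the metabolite with a real effect survives the Bonferroni correction:
MOP's per-SD odds ratio is estimated at 1.60 (the generating value), while
MEHP's nominal p of 0.019 is correctly absorbed by the family-wise
correction.

```r
validate_selfreport(cohort, design)$agreement
#> Agreement 94.27%, kappa = 0.7433 (SE 0.0391, p = 1.05e-80), n = 646
#> Design-weighted: agreement 93.17%, kappa = 0.6923

run_misclass_mc(cohort, design,
                mc_config(fp_rate = 0.112, fn_rate = 0.0492,
                          n_replicates = 200, seed = 2026))
#> Misclassification MC: 200 replicates, mean beta = 0.3961 (SD 0.0765)
#> OR = 1.49 (95% CI 1.28-1.73)
```

Reshuffling cases and controls at the validation-derived misclassification
rates attenuates the estimate toward the null (1.49 < 1.60) but the CI stays
clear of 1 — the association is robust to outcome error of that magnitude.

```r
dose_response(cohort$z_MOP, cohort$selfreport_outcome, design)
#>         bin   n positives prevalence_raw prevalence_weighted prevalence_se
#> 1   <=-1 SD 359        26     0.07242340          0.07414133    0.01731897
#> 2 (-1,0] SD 775        68     0.08774194          0.08236332    0.01243453
#> 3  (0,1] SD 774       116     0.14987080          0.14996978    0.01987268
#> 4    >+1 SD 359        78     0.21727019          0.21731314    0.02221839
#> Cochran-Armitage trend: chi2(1) = 46.901, p = 7.468e-12
```

Design-corrected prevalence climbs from 7.4% in the lowest exposure bin to
21.7% in the highest, and the trend test rejects flatness decisively.

`run_pipeline(pipeline_config(cohort_or_csv, "out/"))` chains all stages
(inclusion → transform → scan → nested models → validation →
misclassification MC → dose-response) and writes one CSV per stage plus a
text report; `inst/scripts/run-analysis.R` is a thin command-line wrapper.

## Data expectations

Cohort tables are plain data frames (CSV round trip via
`write_cohort_csv()` / `read_cohort_csv()`): design columns
(`stratum_label`, `psu_label`, `sampling_weight`), one concentration column
per metabolite (ng/mL) with `below_lod_<name>` flags, `creatinine` (mg/dL),
coded confounders (see `default_covariate_coding()`; missing always codes to
0), eligibility fields (`dm_selfreport`, `insulin`, `pills`, `hba1c`,
`age_screening`, `age_diagnosis`), `selfreport_outcome` (0/1), and
`imaging_grade` (`none`/`mild`/`modsev`/`PR`, `NA` outside the validation
subsample). `inst/extdata/synthetic_cohort_n200.csv` is a small synthetic
example produced by `generate_cohort()`;
`inst/extdata/validation_subsample_counts.csv` holds the published
validation cross-tabulation counts for an NHANES diabetic subsample
(n = 285).

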
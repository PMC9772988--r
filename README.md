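# cgmrisk

Time-in-range glycometrics and distributional CGM analysis for 5-year
type 2 diabetes risk.

## The problem

Continuous glucose monitoring (CGM) records interstitial glucose every
5 minutes (288 readings/day, 40–400 mg/dL). In adults *without* diabetes,
the fraction of monitoring time spent above the normal range — **time
above range**, `TAR = % of readings > 140 mg/dL` — captures post-prandial
glucose spikes that a single HbA1c or fasting glucose misses, and is a
candidate prognostic marker for progression to type 2 diabetes (T2D).
`cgmrisk` is for epidemiologists and biostatisticians analysing such
cohorts: it takes a baseline cohort table and long-format CGM traces and
produces wear-time summaries, range metrics, glucodensity comparisons,
clinical classifications, incidence estimates and an adjusted risk model.

## What it computes

* **Range metrics** per subject over complete wear days (a day is complete
  at ≥ 80% of 288 samples; eligibility needs ≥ 2 complete days):

  `TIR = %[70, 140] mg/dL`, `TAR = % > 140`, `TBR = % < 70`,
  with `TIR + TAR + TBR = 100`.

* **Glucodensities**: each subject's glucose distribution as a kernel
  density on [40, 400] mg/dL, compared via the 1-D 2-Wasserstein metric
  `W2(F, G) = ( ∫₀¹ (F⁻¹(p) − G⁻¹(p))² dp )^{1/2}`, group barycenters
  (quantile-function means), and a permutation test on the squared
  barycenter distance.

* **Clinical criteria**: ADA diagnosis (FPG ≥ 126 mg/dL or HbA1c ≥ 6.5%,
  confirmed in a second sample unless hyperglycaemia is unequivocal),
  incident-T2D ascertainment (follow-up labs or physician record),
  ATP-III metabolic syndrome (≥ 3 of 5 components, printed sex-specific
  cut-offs), `HOMA-IR = insulin(μU/mL) × glucose(mmol/L)/22.5`, and the
  NGSP→IFCC master equation `(HbA1c% − 2.15) × 10.929`.

* **Incidence & prediction**: cumulative incidence, exact (Garwood)
  Poisson intervals for rates per 1,000 person-years, chi-square /
  Mann–Whitney group comparisons, and the adjusted logistic model

  `logit P(T2D in 5y) = β₀ + β₁ age + β₂ sex + β₃ family history + β₄ BMI + β₅ HbA1c + β₆ TAR`,

  with odds ratios (Wald 95% CI), apparent ROC AUC (DeLong CI) and Brier
  score, via broom-style `tidy()`/`glance()` and `autoplot()`.

* **A calibrated synthetic cohort generator** — group-conditional
  truncated marginals, a Gaussian copula on (HbA1c, FPG, TAR propensity,
  BMI), and a circadian + meal-excursion + AR(1) trace model whose
  per-subject amplitude is solved so expected TAR matches a latent
  propensity. Defaults encode a 499-subject population cohort with 22
  progressors (TAR medians 1.9% vs 7.8%). A causal-logistic mode exists
  for parameter-recovery studies.

## Worked example

```r
library(cgmrisk)

cfg     <- cohort_config(seed = 2026)        # 499 subjects, 22 progressors
cohort  <- generate_cohort(cfg)
metrics <- simulate_range_metrics(cohort, cfg)   # per-subject TIR/TAR/TBR
analysed <- dplyr::inner_join(cohort, metrics, by = "subject_id")

compare_groups(analysed, "outcome_t2d_5y", c(tar_pct = "mannwhitney"))
#>   variable test         summary_control          summary_case     p_value
#>   tar_pct  Mann-Whitney 1.6 [0.3, 5.0] | 4.2 ... 9.9 [4.7, 1...   7.41e-8

fit_risk_model(analysed)
#> Adjusted logistic model for 5-year incident type 2 diabetes
#>   n = 499 subjects, 22 events
#>   age                    OR  1.04 (1.00, 1.08)  p = 0.0545
#>   sexmale                OR  1.36 (0.48, 3.90)  p = 0.564
#>   family_history_dmTRUE  OR  0.94 (0.34, 2.59)  p = 0.909
#>   bmi                    OR  1.18 (1.06, 1.32)  p = 0.00329
#>   hba1c                  OR 14.63 (3.51, 60.96)  p = 0.000229
#>   tar_pct                OR  1.05 (1.01, 1.10)  p = 0.0126
#>   AUC = 0.85 (0.73, 0.98); Brier score = 0.029
```

Each additional percentage point of baseline TAR multiplies the odds of
developing diabetes within five years by ~1.05 after adjustment for age,
sex, family history, BMI and HbA1c; the model separates progressors from
non-progressors with apparent AUC 0.85 on this simulated cohort.

Incidence bookkeeping on the same cohort:

```r
poisson_rate_ci(22, person_years_fixed_horizon(499, 22), n_at_risk = 499)
#>   events n_at_risk person_years cumulative_incidence_pct rate_per_1000py ci_lo ci_hi
#>       22       499         2440                     4.41            9.02  5.65  13.7
hba1c_ngsp_to_ifcc(5.8)
#> [1] 39.9
```

22 events among 499 subjects is a 4.4% cumulative incidence; with the
half-horizon convention for progressors the exact Poisson interval for the
rate is 5.7–13.7 per 1,000 person-years.

An end-to-end run (simulate → filter → metrics → densities → criteria →
incidence → model → report) is one call:

```r
report <- simulate_study(cohort_config(n_subjects = 60, n_progressors = 6,
                                       seed = 42))
write_report_bundle(report, "report/")
```

or, from a shell,
`Rscript inst/scripts/cgmrisk-pipeline.R simulate --seed 42 --out report/`
(`analyze --cohort cohort.csv --cgm traces.csv` for real data).

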
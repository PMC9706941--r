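# failtiming

Failure-timing survival analysis for locoregionally advanced
nasopharyngeal carcinoma (LANPC) cohorts treated with induction
chemotherapy and radiotherapy, with or without concurrent cisplatin.

The package is aimed at clinical biostatisticians who want the full
"early versus late treatment failure" analysis as tested, reusable
components rather than a one-off script:

* **Endpoints** — overall survival (OS), failure-free survival (FFS),
  locoregional / distant failure-free survival (LRFFS / DFFS) and
  post-failure OS, derived from a per-patient cohort table.
* **Minimum-P cut-point scan** — for each integer-month candidate
  threshold *c*, the failure cohort is split into early
  (failure within *c* months) and late failures, the post-failure
  survival difference is tested by the log-rank statistic, and the
  threshold with the smallest P is selected:
  `ĉ = argmin_c p_logrank(c)`.  Because the minimum over a scan of
  correlated tests is anti-conservative, the minimum P is corrected
  against its permutation (or bootstrap) null distribution with the
  add-one estimator `(1 + #{min P_b ≤ min P_obs}) / (B + 1)`.
* **Cox proportional-hazards models** — damped-Newton partial-likelihood
  maximisation (Efron ties by default), univariable screening at
  P < 0.10 followed by backward elimination to P < 0.05, with block Wald
  tests for multi-level factors and a full elimination trace.
* **Random survival forest** — bootstrap survival trees with log-rank
  splits and Nelson–Aalen terminal nodes (compiled core); predictions
  average cumulative hazards, `F(t) = 1 − exp(−H̄(t))`.  Dose-group
  curves are adjusted by g-computation over the cohort's covariate
  distribution, and monthly time-specific failure probabilities are the
  smoothed discrete derivative of `F`, rescaled to conserve mass at the
  horizon.
* **Synthetic cohorts** — a calibrated generator with published
  covariate marginals, piecewise-constant hazards, a configurable
  early/late change-point (14 months locoregional, 20 months distant by
  default) and dose-group effects (CCD > 200 mg/m² multiplies the early
  distant-failure hazard by 0.351), plus a deterministic integration
  oracle for its expected event fractions.

## Worked example

```r
library(failtiming)

params <- default_params(n_patients = 3123, seed = 1)
cohort <- generate_cohort(params)

## distant-failure cohort: scan thresholds, correct the minimum P
fc   <- failure_cohort(cohort, "df")
grid <- admissible_grid(fc$interval, fc$death)
scan <- correct_min_p(fc, grid, n_resamples = 1000, seed = 2)
print(scan)
#> <cutpoint_scan> n = 543 failures, 42 admissible of 42 candidates
#>   selected cut-off: 20 months, min p = 1.274e-17
#>   corrected p = 0.000999 (permutation, 1000 resamples)
```

The scan recovers the generator's built-in 20-month distant change-point,
and the corrected P says the early/late split is far beyond what scanning
42 thresholds under the null could produce.

```r
## multivariable model for early distant failure (events within 20 months)
ep  <- derive_endpoints(cohort)
co  <- scan$selected_cutoff
fit <- backward_eliminate(
  pmin(ep$dffs_time, co),
  as.numeric(ep$dffs_event == 1 & ep$dffs_time <= co),
  cohort,
  c("sex", "histology", "age_group", "family_history", "t_stage",
    "n_stage", "overall_stage", "ebv_dna", "ic_cycles", "ccd_group"))
print(fit)
#> <cox_fit> n = 3123 ( 284 events ), ties: efron
#>          contrast    coef hazard_ratio lower95 upper95  p_value
#>           sexMale -0.2690        0.764 0.59507  0.9813 3.51e-02
#>       n_stageN2-3  0.7556        2.129 1.64991  2.7472 6.26e-09
#>  overall_stageIVa  0.3370        1.401 1.10583  1.7742 5.21e-03
#>     ebv_dna>=4000  0.3022        1.353 1.05976  1.7270 1.53e-02
#>    ccd_group1-200 -0.3488        0.706 0.54758  0.9091 6.99e-03
#>     ccd_group>200 -1.4953        0.224 0.09101  0.5523 1.15e-03
```

Advanced nodal stage, stage IVa and high EBV DNA load raise the early
distant-failure hazard; concurrent cisplatin is protective, strongly so
above 200 mg/m² (this cohort realisation estimates HR 0.22 for a
generating value of 0.351).

```r
km <- km_estimate(ep$os_time, ep$os_event)
cat(sprintf("5-year overall survival: %.1f%%\n", 100 * survival_at(km, 60)))
#> 5-year overall survival: 82.0%
```

`run_pipeline(analysis_config(...))` executes the whole analysis —
baseline table, both cut-point scans, early/late and dose-group
Kaplan–Meier summaries, eight Cox tables, and adjusted forest curves —
and writes a byte-reproducible JSON report plus tidy CSVs.  A thin
command-line front end with `simulate`, `cutpoint`, `cox`, `rsf`, `run`
and `schema` subcommands ships in `inst/cli/failtiming.R`.

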
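# pkipr

Early prediction and adjudication of acute kidney injury (AKI) in acute
pesticide poisoning cohorts.

Patients who ingest pesticides are at substantial risk of AKI, and AKI in
this population carries a large excess mortality. `pkipr` implements the
computational core of an early-warning workflow for this setting, aimed at
clinical epidemiologists and biostatisticians working with time-stamped
electronic-health-record extracts:

1. **KDIGO adjudication engine** — labels AKI presence, stage (1–3), onset
   hour and triggering criterion from longitudinal serum-creatinine (sCr),
   urine-output (UO) and dialysis records. Baseline sCr is *dynamic*: for a
   measurement at time *t*, the baseline is the minimum sCr in the half-open
   window *[t − L, t)* with *L* = 48 h for the absolute criterion
   (ΔsCr ≥ 0.3 mg/dL) and *L* = 168 h for the ratio criterion (stage 1:
   1.5 ≤ r < 2.0; stage 2: 2.0 ≤ r < 3.0; stage 3: r ≥ 3.0 × baseline);
   when no earlier value exists, the minimum sCr of the first 2 h
   substitutes. UO criteria use weight-normalised moving windows (stage 1:
   < 0.5 mL/kg/h over 6 h; stage 2: < 0.5 over 12 h; stage 3: < 0.3 over
   24 h or anuria ≥ 12 h); initiation of maintenance dialysis is stage 3.
   The final stage is the highest across criteria within 168 h, the onset
   the earliest, and labels that exist only because a transient first-2-h
   sCr dip was accepted as baseline are flagged *ambiguous*.
2. **Cohort filters** — adults only, no paraquat, definable baseline,
   baseline sCr ≤ 2.5 mg/dL, no event within 2 h of presentation.
3. **Feature pipeline** — per-variable maximum over the first 2 h, mode
   imputation for categoricals, seeded chained-equations imputation for
   numerics, robust scaling (x − median)/IQR, with strictly
   training-fold-fitted transforms for held-out rows.
4. **Risk model** — univariate Cox screen (p < 0.1), feature selection
   (full / clinical / stepwise / LASSO), stratified 5-fold cross-validated
   classifiers (penalised logistic and gradient-boosted references, grid
   search by pooled out-of-fold AUROC), accuracy-optimal threshold,
   calibration table and Brier score.
5. **Risk stratification** — five groups (minimal/low/moderate/high/severe,
   top cut 0.43) with Kaplan–Meier curves, pairwise log-rank tests,
   Cochran–Armitage trend tests and Cox hazard ratios against the moderate
   group, for both AKI occurrence and mortality.
6. **Synthetic cohort generator** — time-stamped cohorts with known ground
   truth (latent logistic risk on 13 features, injected sCr/UO episodes,
   stage-dependent mortality, missingness), so the whole pipeline is
   testable end to end without access to protected hospital data.

## Worked example

```r
library(pkipr)

res <- run_pipeline(
  run_config(seed = 11, generator = generator_params(n_patients = 2000, seed = 11)),
  out_dir = "pkip_run"
)

glance(res$cv)
#> # A tibble: 1 × 13
#>   learner      auroc auroc_lo auroc_hi auprc auprc_lo auprc_hi brier threshold ...
#> 1 ref-logistic 0.775    0.753    0.795 0.579    0.536    0.619 0.170     0.366 ...

tidy(res$stratification)
#> # A tibble: 4 × 4
#>   group        n   aki deaths
#> 1 low        298    14     16
#> 2 moderate   870   157    70
#> 3 high       526   221    44
#> 4 severe     306   187    48
```

(No patient of this cohort lands in the minimal group: the fitted
out-of-fold probabilities never drop below its 0.05 upper cut.)

The pooled out-of-fold AUROC of 0.775 sits close to the generating
Bayes-optimal discrimination of 0.80 built into the simulated cohort (the
gap reflects finite-sample fitting, missingness and imputation). The
stratification table shows the monotone risk gradient across the five
groups — the basis of the trend tests and the hazard-ratio forest data
written to the run directory. `plot_km()`, `plot_calibration()` and
`plot_forest()` draw the matching figures.

Individual stages are ordinary tibble-in/tibble-out functions:
`simulate_cohort()`, `apply_cohort_filters()`, `adjudicate_cohort()`,
`aggregate_first_window()`, `impute_features()`, `robust_scale()`,
`univariate_cox_screen()`, `select_features()`, `train_cv()`,
`risk_stratification()`.

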
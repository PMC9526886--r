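# radsens

Intrinsic radiosensitivity (IRS) indices from γH2AX flow cytometry, with a
statistical layer for predicting acute radiotherapy skin toxicity.

## The problem

Patients receiving identical radiotherapy schedules differ widely in how
much acute normal-tissue damage they suffer. A candidate pre-treatment
biomarker is the DNA double-strand-break (DSB) response of a patient's own
lymphocytes: blood cells are irradiated *in vitro* (0, 1 and 2 Gy), and the
phosphorylated histone γH2AX — which accumulates at DSBs — is measured by
flow cytometry at 30 min (peak induction), 3 h and 24 h (repair). Patients
whose cells form more damage per Gy, or repair it more slowly, tend to be
the clinical "overreactors" (RTOG acute skin toxicity grade ≥ 2).

`radsens` implements that analysis end to end for researchers working with
event-level cytometry data:

* **Cytometry** — read event tables (CSV dialect or FCS 3.0/3.1 list mode),
  apply a declarative lymphocyte scatter gate, and compute the geometric
  mean fluorescence `exp(mean(log x))` per sample (`read_events()`,
  `gate_spec()`, `apply_gate()`, `geometric_mean()`, `summarise_gm()`).
* **Indices** — per patient *p* with geometric means GM(*D*, *t*):
  - DSB induction: `GM(D, 30 min) − GM(control)`
  - residual damage: `100 · [GM(D, t) − GM(ctrl)] / [GM(D, 30 min) − GM(ctrl)]`
    for *t* = 3 h, 24 h
  - dose-response slope: OLS slope of `GM(D, 30 min) − GM(ctrl)` on *D*

  (`dsb_induction()`, `residual_pct()`, `dose_response_slope()`,
  `irs_index_table()`).
* **Prediction** — Pearson correlation with toxicity grade, KS Gaussian
  fit, Gaussian-centile thresholds (mean + *k*·SD, *k* ∈ {1, 2}, i.e. the
  68th/95th centiles), confusion-matrix metrics, and ROC curves with the
  Youden-optimal cutoff and Mann–Whitney-consistent AUC
  (`pearson_cor()`, `ks_normality()`, `gaussian_threshold()`,
  `classify_and_score()`, `roc_analysis()`, `roc_auc_ci()`).
* **Film dosimetry** — radiochromic-film surface doses from red-channel
  pixel values: `netOD = log10(PV_unexposed / PV_exposed)`, calibrated
  through `dose = a·netOD + b·netOD^n` (`net_od()`, `fit_calibration()`,
  `film_dose()`, `patient_surface_dose()`).
* **Synthetic cohorts** — a fully seeded generator producing event-level
  data with the structure the analysis assumes (log-normal per-event
  fluorescence, linear induction, exponential repair, grade coupled to a
  latent sensitivity, surface dose independent of grade), so the whole
  pipeline is testable without patient data (`cohort_config()`,
  `simulate_cohort()`, `write_cohort()`).

Everything is tibble-in / tibble-out and pipe-friendly; fitted objects have
`tidy()`/`glance()` methods and `autoplot()`/`plot_*()` figures.

## Worked example

```r
library(radsens)

cfg    <- cohort_config(n_patients = 50, events_per_sample = 2000, seed = 7)
report <- run_study(config = cfg)
report
#> <irs_report> 50 patients; 36.0% grade >= 2
#>   cohort dose-response: slope 12.18, r2 1.0000; ANOVA p = 7.87e-34
#>   Pearson r vs grade:
#>     dsb_2gy            r = +0.805 (p = 1.9e-12, n = 50)
#>     residual3h_pct     r = +0.497 (p = 0.00024, n = 50)
#>     residual24h_pct    r = +0.373 (p = 0.0076, n = 50)
#>     slope              r = +0.805 (p = 1.9e-12, n = 50)
#>     surface_dose       r = -0.140 (p = 0.33, n = 50)
#>   ROC AUC (Youden cutoff):
#>     dsb_2gy            AUC = 0.929, cutoff = 25.3
#>     residual3h_pct     AUC = 0.748, cutoff = 72.5
#>     residual24h_pct    AUC = 0.745, cutoff = 6.14
#>     slope              AUC = 0.929, cutoff = 12.7
```

Reading this: the simulated cohort reproduces the structure such a study
expects — a near-perfect linear mean dose-response (r² ≈ 1.00), a strong
positive correlation between each damage index and observed skin toxicity,
no association between delivered surface dose and toxicity (the toxicity
differences are intrinsic, not dosimetric), and a dose-response slope that
discriminates overreactors from normal reactors (AUC ≈ 0.93). Per-patient
indices live in `report$index_table`:

```r
report$index_table[1:4, c("patient_id", "rtog_grade", "dsb_2gy",
                          "residual3h_pct", "residual24h_pct", "slope")]
#>   patient_id rtog_grade dsb_2gy residual3h_pct residual24h_pct slope
#> 1 P001                1    12.3           36.9           -3.64  6.15
#> 2 P002                0    10.1           26.6           -1.46  5.05
#> 3 P003                3    53.0           76.8           12.8  26.5
#> 4 P004                2    36.6           78.4           10.6  18.3

glance(report$roc$slope)
#>     auc optimal_cutoff optimal_sensitivity optimal_specificity ...
#> 1 0.929           12.7               0.889               0.812
```

`autoplot(report$roc$slope)`, `plot_dose_response(report$gm_table)` and
`plot_index_heatmap(report$index_table)` draw the standard figures.
`run_study(events_dir = ...)` runs the identical analysis on a directory of
measured event files plus a `cohort_metadata.csv` (see `write_cohort()` for
the file dialect).

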
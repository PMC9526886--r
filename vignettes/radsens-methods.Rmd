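---
title: "Methods: gamma-H2AX radiosensitivity indices and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gamma-H2AX radiosensitivity indices and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(radsens)
```

## The measurement and the model

The assay irradiates a patient's peripheral blood mononuclear cells *in
vitro* at 0, 1 and 2 Gy and measures γH2AX immunofluorescence per cell by
flow cytometry at 30 min, 3 h and 24 h after exposure. γH2AX marks DNA
double-strand breaks, so the per-sample summary — the geometric mean of the
per-event FITC signal — tracks the damage burden. The geometric mean is the
standard location statistic here because per-event fluorescence is
approximately log-normal; `radsens` computes it as `exp(mean(log x))` over
the gated, positive intensities.

Three per-patient indices are derived from the grid of geometric means
GM(dose, time):

* **DSB induction** at dose *D*: `GM(D, 30 min) − GM(control)`, in
  geometric-mean fluorescence units. The unirradiated tube at the induction
  timepoint serves as the control cell throughout; other dose-0 tubes are
  carried but not used as background, which keeps every index anchored to a
  single, well-defined baseline.
* **Residual damage** at *t* ∈ {3 h, 24 h}:
  `100·[GM(D, t) − GM(ctrl)] / [GM(D, 30 min) − GM(ctrl)]` percent. Values
  are reported at the 2 Gy tube by default, where the signal-to-noise of the
  denominator is best. If the denominator is ≤ `tol` (default 1e−9) the
  value is undefined: it is returned as `NA`, counted, and dropped pairwise
  from any correlation — never imputed or clamped.
* **Dose-response slope**: the OLS slope of `GM(D, 30 min) − GM(ctrl)`
  against *D*, in GM units per Gy, with `r²` as fit quality. The
  normalisation is a subtraction rather than a ratio so that the slope and
  the induction index live on the same scale. The fit keeps an intercept
  even though the normalised response is exactly zero at 0 Gy; with real
  (noisy) control tubes the intercept absorbs baseline error instead of
  leaking it into the slope.

One structural fact worth knowing: with the standard dose grid {0, 1, 2} Gy
and the control-anchored response (y(0) ≡ 0), the OLS slope reduces
algebraically to half the 2 Gy induction — the centre point has zero leverage
in a three-point symmetric design. The slope and the 2 Gy induction are then
perfectly collinear and correlate identically with any outcome. They
separate only with more dose levels, a different normalisation, or noise in
the 0 Gy anchor; the package implements the defining formulas as stated and
leaves that distinction to the data.

## The prediction layer

Clinical radiosensitivity enters as the RTOG acute skin toxicity grade
(ordinal 0–4); "overreactors" are grade ≥ 2 and form the positive class
(configurable). The statistical layer is deliberately classical:

* **Correlation**: Pearson product-moment *r* with a two-sided p-value from
  the *t* transform on n − 2 degrees of freedom (`stats::cor.test` behind
  the interface). Zero variance is an error, not r = 0.
* **Normality**: Kolmogorov–Smirnov distance against a Gaussian with the
  sample mean and SD, plus the R² of a Gaussian density over the sample
  histogram. The asymptotic KS p-value is used without the Lilliefors
  correction for estimated parameters, matching what general-purpose
  statistics software does by default; since the uncorrected p is biased
  upward, it can only make this descriptive check conservative.
* **Gaussian-centile thresholds**: under a Gaussian model, 68% of the
  population lies within one SD of the mean and 95% within two. Because
  only overreaction is clinically positive, the two-sided band collapses to
  a one-sided cutoff `mean + k·SD` (k = 1 or 2) for indices where high
  values mean sensitive. The SD uses the n − 1 denominator.
* **Classifier metrics**: sensitivity, specificity, accuracy, PPV and NPV
  in percent, straight from the 2×2 counts. A ratio with a zero denominator
  is reported as `NA` ("undefined"), never as 0 — an all-negative
  classifier has an undefined PPV, not a perfect one. Note that whenever
  specificity is 100% (no false positives) the PPV is forced to 100% by
  definition; the package always reports the value computed from its own
  counts.
* **ROC**: thresholds at every distinct score value; the curve is swept
  with the "predict positive iff score ≥ t" convention. The AUC is the
  trapezoid area, which — because tied scores contribute diagonal
  segments — equals the Mann–Whitney pair-counting statistic exactly (the
  test suite asserts this identity against an exhaustive pair-counting
  oracle). The reported optimal cutoff maximises the Youden index
  J = sensitivity + specificity − 1, the conventional formalisation of
  "most predictive" when no cost ratio is given; J-ties are broken toward
  higher specificity (a screening assay should not cry wolf). A stratified
  bootstrap CI for the AUC (`roc_auc_ci()`, 2000 resamples by default,
  seeded) is provided as an engineering aid beyond the core analysis.
* **ANOVA**: classical one-way ANOVA of the 30-min geometric means across
  dose groups (`stats::aov`).

## Film dosimetry

Surface dose is measured with radiochromic film at three positions (medial,
lateral, central). The module starts from mean red-channel ROI pixel
values — image segmentation is upstream of it — and applies the standard
red-channel workflow: `netOD = log10(PV_unexposed / PV_exposed)`, then a
power-law calibration `dose = a·netOD + b·netOD^n` with no intercept (blank
film must map to zero dose). The exponent may be fitted (bounded > 1) or
fixed at 2.5, a common red-channel choice for doses up to ~10 Gy. Fits are
rejected unless monotone nondecreasing on a dense grid over the calibration
domain, since a non-invertible calibration is unusable. No background or
glass-scan correction terms are modelled.

## The synthetic cohort generator

No per-patient raw data are distributed with the assay description, so the
package ships a generator whose defaults *are* the study conditions it
emulates: 50 patients, doses {0, 1, 2} Gy, timepoints {0.5, 3, 24} h,
10 000 events per tube. Per patient:

* latent induction slope (sensitivity) ~ Normal(15, 7) GM units/Gy,
  truncated positive. The mean and spread are chosen so the cohort spans
  weak to strong responders on the scale such assays report;
* baseline geometric mean ~ Normal(20, 3) fluorescence units;
* repair half-life ~ Normal(5, 2) h, truncated, correlated with the
  sensitivity latent through a Gaussian copula (`repair_coupling = 0.6`):
  patients who form more damage also tend to repair it more slowly. This
  single knob is what makes the residual-damage indices clinically
  informative in simulation, as they are in real cohorts; setting it to 0
  makes residuals pure repair noise;
* RTOG grade = number of `grade_cutpoints` below (sensitivity + ordinal
  noise). The default cutpoints (0.5, 18.1, 27.1, 60) are calibrated so the
  *marginal* grade distribution under the default latents is ≈ 64% grades
  0–1, 28% grade 2, 8% grade 3, with grades 0 and 4 rare — the kind of
  skew an unselected breast-RT cohort shows. `grade_noise_sd = 5` makes the
  index–grade correlations strong but imperfect (r ≈ 0.6–0.7 rather than
  ≈ 0.85 at the noise-free limit); `couple_grade = FALSE` severs the link
  entirely for null experiments;
* three surface doses ~ Uniform(0.92, 1.9) Gy, independent of grade by
  construction, so dose–toxicity correlations are null.

Per event, the FITC intensity is log-normal around the generative geometric
mean `baseline + sensitivity·D·ρ(t)`, where ρ = 1 at 30 min and
ρ(t) = 2^(−(t − 0.5)/halflife) afterwards — induction is anchored at the
first timepoint, and repair is first-order decay. `event_cv = 0.8` sets the
per-event coefficient of variation (broad, as γH2AX histograms are);
`event_cv = 0` is the exact noise-free limit used by tests. Scatter
channels are two Gaussian clusters — lymphocytes at (FSC 400, SSC 200) and
a 5% debris fraction at low scatter carrying only autofluorescence — so
gating has something real to remove. The PI channel is populated but unused
by the indices.

Every tube derives its own RNG seed deterministically from the
configuration seed, which has two consequences: the same configuration is
bit-identical across runs, and `simulate_gm_table()` can regenerate,
summarise and discard one tube at a time, producing exactly the table the
materialised cohort would give while holding ~10⁴ events in memory instead
of ~10⁶–10⁷.

What the generator does *not* emulate: cell-cycle structure and DNA-content
histograms, apoptotic subpopulations, spectral spillover and compensation
artefacts, inter-batch and inter-instrument effects, and any dependence of
surface dose on anatomy. Tests passing on synthetic cohorts therefore
demonstrate that the estimators recover the structure they assume — not
that real cytometry is free of the distortions above.

## Numerical and interface choices

* Nonpositive event intensities (possible after compensation): default
  policy excludes them with a recorded count; a `shift_epsilon` policy
  (translate so the minimum equals ε) exists for small fixtures. The
  geometric mean is undefined without at least one positive value.
* Gating is declarative (`none`, `rectangle`, `ellipse` inscribed in its
  bounding box) rather than interactive, trading fidelity to GUI workflows
  for reproducibility; `mode = "none"` is the correct default for clean
  synthetic data. Channel roles resolve from an explicit mapping first and
  name patterns second; ambiguity is an error, never a guess.
* Negative induction (30-min GM below control) is kept with a warning.
* File dialects: per-tube CSV `FSC,SSC,FITC,PI` named
  `{patient}_{dose}Gy_{time}h.csv`, plus `cohort_metadata.csv`; a minimal
  FCS 3.1 list-mode reader/writer (float32, little-endian, `$PnN` names)
  covers instrument-style files and round-trips the CSV dialect to ~1e−7
  relative, the precision of 32-bit storage.
* Youden ties are compared with a 1e−12 tolerance because J values like
  2/3 can differ by one ulp depending on the arithmetic path.

## Validation strategy and problem sizes

The test suite separates frozen worked examples (hand-computable numbers),
property checks (invariance under rescaling, gate monotonicity, ROC
direction symmetry, metric identities), and oracle equivalence: geometric
mean, OLS slope, Pearson r, one-way ANOVA F, 2×2 metrics and AUC are each
compared against independent brute-force implementations (log-sum, explicit
covariance sums, sums-of-squares decomposition, exhaustive pair counting)
on 1000 random small instances at 1e−10 relative tolerance. Parameter
recovery uses a 200-patient cohort at 10 000 events per tube (slope vs
latent sensitivity, r > 0.95) and a 60-patient cohort at 1000 vs 10 000
events to show the estimation error shrinking; null behaviour uses a
500-patient uncoupled cohort (|r| < 0.1, bootstrap AUC CI covering 0.5).
These sizes keep the full suite around two minutes on one core while
leaving the Monte-Carlo margins comfortable.

## Known limitations

* The grade model is a cutpoint coarsening of one latent dimension; real
  toxicity grading has inter-rater noise and multi-factor drivers.
* Residual percentages inherit the variance of a ratio of differences;
  at low induction they are unstable, which is why undefined and negative
  values are surfaced rather than smoothed away.
* The KS p-value is conservative by construction (see above); treat it as
  descriptive, not confirmatory.
* Film calibration covers the single-scan red-channel protocol only — no
  triple-channel dosimetry, lateral scanner correction, or dose maps.
* With three evenly spaced doses the slope index adds no discriminative
  information beyond the 2 Gy induction (they are collinear); its value is
  interpretability and robustness of the fitting interface when more dose
  levels are available.
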
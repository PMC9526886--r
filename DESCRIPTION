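Package: radsens
Title: Intrinsic Radiosensitivity Indices from Gamma-H2AX Flow Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies intrinsic radiosensitivity of patients from event-level
    flow-cytometry measurements of gamma-H2AX, a phosphorylated histone that
    marks DNA double-strand breaks. Computes per-patient double-strand-break
    induction, residual (unrepaired) damage fractions at late timepoints, and
    the slope of the linear dose-response of background-subtracted geometric
    mean fluorescence; derives Gaussian-centile classification thresholds,
    confusion-matrix metrics, and ROC curves with Youden-optimal cutoffs
    against ordinal acute skin toxicity grades; reduces radiochromic-film
    measurements to net optical density and calibrated surface dose; and ships
    a fully reproducible synthetic-cohort simulator so the whole pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
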
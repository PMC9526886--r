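# The three per-patient radiosensitivity indices and the cohort-level
# summaries built from them.

test_that("DSB induction is a plain background subtraction", {
  expect_equal(dsb_induction(25, 25), 0)
  expect_equal(dsb_induction(50, 20), 30)
  expect_warning(out <- dsb_induction(18, 20), "negative induction")
  expect_equal(out, -2) # kept, not clamped
  expect_error(dsb_induction(-1, 20), "positive")
})

test_that("residual percentage matches its defining ratio", {
  expect_equal(residual_pct(20, 50, 20), 0)    # full repair
  expect_equal(residual_pct(50, 50, 20), 100)  # no repair
  # (30 - 20) / (50 - 20) = 1/3 exactly
  expect_equal(residual_pct(30, 50, 20), 100 / 3, tolerance = 1e-12)
  expect_warning(out <- residual_pct(30, 20, 20), "undefined")
  expect_true(is.na(out))
})

test_that("residual percentage is invariant under common rescaling", {
  set.seed(2)
  for (i in 1:100) {
    ctrl <- stats::runif(1, 5, 30)
    g30 <- ctrl + stats::runif(1, 1, 50)
    gl <- ctrl + stats::runif(1, 0, g30 - ctrl)
    a <- stats::runif(1, 0.1, 10)
    expect_rel_equal(residual_pct(a * gl, a * g30, a * ctrl),
                     residual_pct(gl, g30, ctrl), tol = 1e-10)
  }
})

test_that("dose-response slope matches the closed-form OLS oracle", {
  expect_equal(dose_response_slope(c(0, 1, 2), c(20, 35, 50), 20)$slope, 15)
  expect_equal(dose_response_slope(c(0, 1, 2), c(20, 35, 50), 20)$r2, 1)
  expect_equal(dose_response_slope(c(0, 1, 2), c(30, 30, 30), 30)$slope, 0)
  # spec'd worked example: y = (1, 14, 33) at doses (0, 1, 2) -> slope 16
  got <- dose_response_slope(c(0, 1, 2), c(1, 14, 33) + 7, 7)
  expect_equal(got$slope, ols_slope_oracle(c(0, 1, 2), c(1, 14, 33)))
  expect_equal(got$slope, 16)
  expect_error(dose_response_slope(c(1, 1), c(2, 3), 1), "distinct doses")
  set.seed(3)
  for (i in 1:200) {
    x <- stats::runif(sample(3:8, 1), 0, 4)
    if (length(unique(x)) < 2) next
    y <- stats::runif(length(x), 0, 100)
    expect_rel_equal(dose_response_slope(x, y, 0)$slope,
                     ols_slope_oracle(x, y))
  }
})

test_that("index table reproduces the generative parameters when noise-free", {
  cfg <- noise_free_config(induction_slope_sd = 2, baseline_gm_sd = 1,
                           repair_halflife_sd = 1)
  pats <- simulate_patients(cfg)
  idx <- irs_index_table(simulate_gm_table(cfg), meta = pats)
  idx <- idx[order(idx$patient_id), ]
  pats <- pats[order(pats$patient_id), ]
  # induction = sensitivity * dose, slope = sensitivity, r2 = 1
  expect_equal(idx$dsb_1gy, pats$sensitivity, tolerance = 1e-9)
  expect_equal(idx$dsb_2gy, 2 * pats$sensitivity, tolerance = 1e-9)
  expect_equal(idx$slope, pats$sensitivity, tolerance = 1e-9)
  expect_true(all(idx$slope_r2 > 1 - 1e-12))
  # residual% = 100 * 2^(-(t - 0.5)/halflife), independent of dose
  expect_equal(idx$residual3h_pct,
               100 * 2^(-2.5 / pats$repair_halflife), tolerance = 1e-9)
  expect_equal(idx$residual24h_pct,
               100 * 2^(-23.5 / pats$repair_halflife), tolerance = 1e-9)
})

test_that("estimated slopes recover latent sensitivity, improving with events", {
  cfg1 <- cohort_config(n_patients = 60, events_per_sample = 1000, seed = 9)
  cfg2 <- cohort_config(n_patients = 60, events_per_sample = 10000, seed = 9)
  pats <- simulate_patients(cfg1) # latent draws identical for both configs
  err <- function(cfg) {
    idx <- irs_index_table(simulate_gm_table(cfg))
    mean(abs(idx$slope[order(idx$patient_id)] -
               pats$sensitivity[order(pats$patient_id)]))
  }
  e1 <- err(cfg1); e2 <- err(cfg2)
  expect_lt(e2, e1) # more events per tube -> tighter slope estimates
  idx <- irs_index_table(simulate_gm_table(cfg2))
  expect_gt(stats::cor(idx$slope, pats$sensitivity), 0.95)
})

test_that("cohort mean dose-response is linear for a linear generator", {
  cfg <- noise_free_config(induction_slope_sd = 2, baseline_gm_sd = 1)
  gm <- simulate_gm_table(cfg)
  dr <- cohort_dose_response(gm)
  expect_equal(dr$r2, 1, tolerance = 1e-9)
  expect_equal(dr$slope, mean(simulate_patients(cfg)$sensitivity),
               tolerance = 1e-9)
  expect_error(cohort_dose_response(gm[gm$dose_gy == 0, ]), "dose levels")
  expect_error(cohort_dose_response(gm[gm$patient_id == "P001", ]),
               "2 patients")
})

test_that("heatmap matrix has stable shape and ordering", {
  cfg <- tiny_config()
  idx <- irs_index_table(simulate_gm_table(cfg),
                         meta = simulate_patients(cfg))
  hm <- heatmap_matrix(idx)
  expect_equal(names(hm), c("patient_id", "dsb_1gy", "dsb_2gy", "rtog_grade"))
  expect_equal(hm$patient_id, sort(hm$patient_id))
  # CSV round-trip preserves values
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(hm, f)
  back <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(hm), tolerance = 1e-12)
})

test_that("index table demands a complete grid", {
  gm <- simulate_gm_table(tiny_config())
  expect_error(irs_index_table(gm[-1, ]), "missing GM cell")
  expect_error(irs_index_table(gm[gm$dose_gy > 0, ]), "control")
})
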
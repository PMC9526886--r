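# Per-patient intrinsic-radiosensitivity indices derived from gated
# geometric means: DSB induction, residual (unrepaired) damage percentage,
# and the dose-response slope.

#' DSB induction
#'
#' Background-subtracted damage signal: the geometric mean of gamma-H2AX at
#' the induction timepoint (30 min) minus the unirradiated control's
#' geometric mean. Negative values (possible with noisy controls) are kept
#' as-is with a warning — clamping would bias the downstream slope.
#'
#' @param gm_30min,gm_control Positive geometric means (vectorised).
#' @return `gm_30min - gm_control`, in geometric-mean fluorescence units.
#' @export
dsb_induction <- function(gm_30min, gm_control) {
  assert_numeric_vec(gm_30min, "gm_30min")
  assert_numeric_vec(gm_control, "gm_control")
  if (any(gm_30min <= 0) || any(gm_control <= 0)) {
    abort("geometric means must be positive")
  }
  out <- gm_30min - gm_control
  if (any(out < 0)) {
    warn(sprintf("%d negative induction value(s) kept unclamped",
                 sum(out < 0)))
  }
  out
}

#' Residual DSB percentage
#'
#' Fraction of the 30-min induction still present at a later timepoint,
#' in percent:
#' \deqn{100 \cdot \frac{GM(t) - GM(control)}{GM(30\,min) - GM(control)}}
#' High residuals indicate poor repair capacity. When the induction
#' denominator is at or below `tol` the value is undefined and returned as
#' `NA` with a warning (such patients are dropped pairwise from downstream
#' correlations, never imputed).
#'
#' @param gm_late Geometric mean at the late timepoint (3 h or 24 h).
#' @param gm_30min,gm_control Induction and control geometric means.
#' @param tol Absolute tolerance below which the denominator counts as zero.
#' @return Percent residual damage (vectorised; `NA` where undefined).
#' @examples
#' residual_pct(30, 50, 20) # 33.33%
#' @export
residual_pct <- function(gm_late, gm_30min, gm_control, tol = 1e-9) {
  assert_numeric_vec(gm_late, "gm_late")
  denom <- gm_30min - gm_control
  bad <- denom <= tol
  if (any(bad)) {
    warn(sprintf(
      "%d residual value(s) undefined (induction denominator <= %g); NA",
      sum(bad), tol))
  }
  out <- 100 * (gm_late - gm_control) / denom
  out[bad] <- NA_real_
  out
}

#' Per-patient dose-response slope
#'
#' Ordinary least squares of the control-subtracted geometric mean on dose,
#' with intercept. The normalisation is a subtraction (consistent with the
#' induction index being a difference); the intercept is retained even
#' though the normalised response at 0 Gy is 0 by construction, as a guard
#' against noise in the control tube.
#'
#' @param dose_gy Doses in Gy (>= 2 distinct values).
#' @param gm Geometric means at those doses (induction timepoint).
#' @param gm_control Control geometric mean subtracted from `gm`.
#' @return A one-row tibble: `slope` (GM units/Gy), `r2` (`NA` when the
#'   response has zero variance).
#' @examples
#' dose_response_slope(c(0, 1, 2), c(20, 35, 50), 20) # slope 15, r2 1
#' @export
dose_response_slope <- function(dose_gy, gm, gm_control) {
  assert_numeric_vec(dose_gy, "dose_gy")
  assert_numeric_vec(gm, "gm")
  assert_number(gm_control, "gm_control")
  if (length(dose_gy) != length(gm)) {
    abort("`dose_gy` and `gm` must have equal length")
  }
  if (length(unique(dose_gy)) < 2L) {
    abort("need >= 2 distinct doses for a slope")
  }
  y <- gm - gm_control
  fit <- lm(y ~ dose_gy)
  r2 <- if (isTRUE(all.equal(stats::var(y), 0))) NA_real_ else
    suppressWarnings(summary(fit)$r.squared) # perfect fits are expected here
  tibble::tibble(slope = unname(coef(fit)[2]), r2 = r2)
}

#' Cohort-level index table
#'
#' Assembles the full per-patient index table the study reports: induction at
#' each nonzero dose, residual percentages at the late timepoints for the
#' reporting dose, and the dose-response slope with its fit quality. The
#' control cell is the unirradiated tube at the induction timepoint.
#'
#' @param gm_tbl Per-sample geometric means ([summarise_gm()] /
#'   [simulate_gm_table()] output, or any tibble with `patient_id`,
#'   `dose_gy`, `time_h`, `gm`).
#' @param meta Optional cohort metadata with `patient_id` and `rtog_grade`
#'   (plus any surface-dose columns), joined onto the result.
#' @param reporting_dose Dose (Gy) at which residual percentages are
#'   reported; the study reports residuals after 2 Gy.
#' @param induction_time Induction timepoint in hours (default 0.5 = 30 min).
#' @param residual_times Late timepoints (hours) for residual percentages.
#' @return Tibble with one row per patient: `patient_id`, `rtog_grade` (if
#'   `meta` given), `dsb_<d>gy` per nonzero dose, `residual<t>h_pct`,
#'   `slope`, `slope_r2`.
#' @export
irs_index_table <- function(gm_tbl, meta = NULL, reporting_dose = 2,
                            induction_time = 0.5, residual_times = c(3, 24)) {
  need <- c("patient_id", "dose_gy", "time_h", "gm")
  if (!all(need %in% names(gm_tbl))) {
    abort(sprintf("`gm_tbl` must have columns %s", paste(need, collapse = ", ")))
  }
  doses <- sort(unique(gm_tbl$dose_gy))
  if (!0 %in% doses) abort("`gm_tbl` must include the 0 Gy control")
  if (!reporting_dose %in% doses) {
    abort(sprintf("reporting_dose %g not present in `gm_tbl`", reporting_dose))
  }
  nonzero <- doses[doses > 0]

  one_patient <- function(df, key) {
    cell <- function(d, t) {
      v <- df$gm[df$dose_gy == d & df$time_h == t]
      if (length(v) != 1L) {
        abort(sprintf("patient %s: missing GM cell at %g Gy, %g h",
                      key$patient_id, d, t))
      }
      v
    }
    gm_ctrl <- cell(0, induction_time)
    ind <- vapply(nonzero, function(d) cell(d, induction_time) - gm_ctrl,
                  numeric(1))
    res <- vapply(residual_times, function(t) {
      suppressWarnings(
        residual_pct(cell(reporting_dose, t), cell(reporting_dose,
                                                   induction_time), gm_ctrl))
    }, numeric(1))
    sl <- dose_response_slope(doses,
                              vapply(doses, cell, numeric(1),
                                     t = induction_time),
                              gm_ctrl)
    out <- tibble::tibble(!!!setNames(as.list(ind),
                                      sprintf("dsb_%sgy", num_label(nonzero))),
                          !!!setNames(as.list(res),
                                      sprintf("residual%sh_pct",
                                              num_label(residual_times))),
                          slope = sl$slope, slope_r2 = sl$r2)
    out
  }

  idx <- gm_tbl |>
    dplyr::filter(.data$time_h == induction_time | .data$dose_gy ==
                    reporting_dose) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(one_patient) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$patient_id)
  n_undef <- sum(is.na(dplyr::select(idx, dplyr::starts_with("residual"))))
  if (n_undef > 0) {
    inform(sprintf("%d undefined residual value(s) (near-zero induction)",
                   n_undef))
  }
  if (!is.null(meta)) {
    idx <- dplyr::left_join(idx, meta, by = "patient_id") |>
      dplyr::relocate(dplyr::any_of("rtog_grade"), .after = "patient_id")
  }
  idx
}

#' Cohort mean dose-response
#'
#' Arithmetic mean (and SD) of the per-patient 30-min geometric means at each
#' dose, with an OLS fit of mean GM on dose — the cohort-level linearity
#' check (the study observes R^2 = 0.99).
#'
#' @inheritParams irs_index_table
#' @param time Timepoint (h) at which the dose-response is taken.
#' @return `cohort_dose_response` object: list with `$per_dose` (tibble of
#'   `dose_gy`, `mean_gm`, `sd_gm`, `n`), `$slope`, `$r2`.
#' @export
cohort_dose_response <- function(gm_tbl, time = 0.5) {
  df <- dplyr::filter(gm_tbl, .data$time_h == time)
  if (dplyr::n_distinct(df$patient_id) < 2L) abort("need >= 2 patients")
  if (dplyr::n_distinct(df$dose_gy) < 2L) abort("need >= 2 dose levels")
  per_dose <- df |>
    dplyr::group_by(.data$dose_gy) |>
    dplyr::summarise(mean_gm = mean(.data$gm), sd_gm = sd(.data$gm),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$dose_gy)
  fit <- lm(mean_gm ~ dose_gy, data = per_dose)
  r2 <- suppressWarnings(summary(fit)$r.squared) # exact linearity is fine
  structure(list(per_dose = per_dose, slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r2 = r2, time_h = time),
            class = "cohort_dose_response")
}

#' @export
print.cohort_dose_response <- function(x, ...) {
  cat(sprintf(
    "<cohort_dose_response> %s h: slope %.3f GM units/Gy, r2 %.4f\n",
    num_label(x$time_h), x$slope, x$r2))
  print(x$per_dose)
  invisible(x)
}

#' @method glance cohort_dose_response
#' @export
glance.cohort_dose_response <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept, r2 = x$r2,
                 n_doses = nrow(x$per_dose), time_h = x$time_h)
}

#' @method tidy cohort_dose_response
#' @export
tidy.cohort_dose_response <- function(x, ...) x$per_dose

#' Heat-map matrix of induction indices and grade
#'
#' Cohort matrix (patients x induction-per-dose plus grade) in a stable
#' patient order, ready for serialisation or [plot_index_heatmap()].
#'
#' @param index_tbl Output of [irs_index_table()] including `rtog_grade`.
#' @return Tibble ordered by `patient_id` with the `dsb_*` columns and
#'   `rtog_grade`.
#' @export
heatmap_matrix <- function(index_tbl) {
  need <- c("patient_id", "rtog_grade")
  if (!all(need %in% names(index_tbl))) {
    abort("`index_tbl` must have patient_id and rtog_grade")
  }
  index_tbl |>
    dplyr::select("patient_id", dplyr::starts_with("dsb_"), "rtog_grade") |>
    dplyr::arrange(.data$patient_id)
}
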
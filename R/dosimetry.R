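# Radiochromic-film dosimetry: red-channel net optical density and a
# power-law calibration to absorbed surface dose. Inputs are mean ROI pixel
# values (image handling happens upstream of this module), as in the usual
# EBT-3 red-channel workflow. No background or glass-scan correction terms
# are applied.

#' Net optical density of a film piece
#'
#' `log10(pv_unexposed / pv_exposed)` of matched mean red-channel pixel
#' values: darker exposed film gives a larger netOD. Negative values (an
#' exposed piece lighter than its blank) are physically suspect and flagged
#' with a warning but returned unchanged.
#'
#' @param pv_exposed,pv_unexposed Positive mean pixel values (vectorised).
#' @return Unitless net optical density.
#' @examples
#' net_od(20000, 40000) # log10(2) = 0.30103
#' @export
net_od <- function(pv_exposed, pv_unexposed) {
  assert_numeric_vec(pv_exposed, "pv_exposed")
  assert_numeric_vec(pv_unexposed, "pv_unexposed")
  if (any(pv_exposed <= 0) || any(pv_unexposed <= 0)) {
    abort("pixel values must be positive")
  }
  out <- log10(pv_unexposed / pv_exposed)
  if (any(out < 0)) {
    warn(sprintf("%d negative netOD value(s): exposed film lighter than blank",
                 sum(out < 0)))
  }
  out
}

#' Fit a film calibration curve
#'
#' Least-squares fit of the standard radiochromic dose-response model
#' \deqn{dose = a \cdot netOD + b \cdot netOD^{n}}
#' (no intercept: zero netOD maps to zero dose by construction). The
#' exponent `n` may be fitted or fixed (2.5 is a common choice for EBT-3 red
#' channel up to ~10 Gy). The fitted curve must be monotone nondecreasing
#' over the calibration domain; a non-monotone fit is an error.
#'
#' @param cal_tbl Tibble/data frame with columns `net_od` and `dose_gy`
#'   (>= 4 points spanning the intended use range, doses up to ~10 Gy).
#' @param n_fixed If non-`NULL`, fix the exponent at this value (> 1).
#' @return A `film_calibration` object with coefficients `a`, `b`, `n`, the
#'   fit domain and residual summary. Use `predict(fit, net_od)` to convert
#'   measurements to dose.
#' @export
fit_calibration <- function(cal_tbl, n_fixed = NULL) {
  need <- c("net_od", "dose_gy")
  if (!all(need %in% names(cal_tbl))) {
    abort("`cal_tbl` must have columns net_od and dose_gy")
  }
  x <- cal_tbl$net_od; y <- cal_tbl$dose_gy
  if (length(x) < 4L) abort("need >= 4 calibration points")
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(x < 0)) {
    abort("calibration points must be finite with nonnegative netOD")
  }
  a0 <- max(stats::coef(lm(y ~ x - 1))[[1]], 1e-3)
  if (is.null(n_fixed)) {
    fit <- minpack.lm::nlsLM(y ~ a * x + b * x^n,
                             start = list(a = a0, b = a0, n = 2.5),
                             lower = c(a = -Inf, b = -Inf, n = 1.0001),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    assert_number(n_fixed, "n_fixed")
    if (n_fixed <= 1) abort("`n_fixed` must be > 1")
    n <- n_fixed
    fit <- minpack.lm::nlsLM(y ~ a * x + b * x^n,
                             start = list(a = a0, b = a0),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  cf <- coef(fit)
  a <- cf[["a"]]; b <- cf[["b"]]
  n <- if (is.null(n_fixed)) cf[["n"]] else n_fixed
  domain <- range(x)
  grid <- seq(domain[1], domain[2], length.out = 512)
  pred <- a * grid + b * grid^n
  if (any(diff(pred) < -1e-9 * max(abs(pred)))) {
    abort("fitted calibration is not monotone nondecreasing over its domain")
  }
  res <- y - (a * x + b * x^n)
  structure(list(a = a, b = b, n = n, n_fixed = !is.null(n_fixed),
                 domain = domain,
                 residual_summary = c(rmse = sqrt(mean(res^2)),
                                      max_abs = max(abs(res))),
                 n_points = length(x)),
            class = "film_calibration")
}

#' @export
print.film_calibration <- function(x, ...) {
  cat(sprintf(
    "<film_calibration> dose = %.4g*netOD + %.4g*netOD^%.4g%s\n",
    x$a, x$b, x$n, if (x$n_fixed) " (n fixed)" else ""))
  cat(sprintf("  domain netOD [%.4g, %.4g], %d points, RMSE %.3g Gy\n",
              x$domain[1], x$domain[2], x$n_points,
              x$residual_summary[["rmse"]]))
  invisible(x)
}

#' @export
predict.film_calibration <- function(object, net_od, ...) {
  assert_numeric_vec(net_od, "net_od")
  if (any(net_od < object$domain[1] - 1e-12 |
          net_od > object$domain[2] + 1e-12)) {
    warn("netOD outside the calibration domain: extrapolating")
  }
  object$a * net_od + object$b * net_od^object$n
}

#' @method tidy film_calibration
#' @export
tidy.film_calibration <- function(x, ...) {
  tibble::tibble(term = c("a", "b", "n"),
                 estimate = c(x$a, x$b, x$n),
                 fixed = c(FALSE, FALSE, x$n_fixed))
}

#' @method glance film_calibration
#' @export
glance.film_calibration <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, n = x$n, n_points = x$n_points,
                 domain_lo = x$domain[1], domain_hi = x$domain[2],
                 rmse = x$residual_summary[["rmse"]])
}

#' Reduce film measurements to calibrated dose
#'
#' @param film_tbl Tibble with `patient_id`, `position` (one of `medial`,
#'   `lateral`, `central`), `pv_exposed`, `pv_unexposed`.
#' @param calibration A [fit_calibration()] result.
#' @return `film_tbl` with `net_od` and `dose_gy` columns appended.
#' @export
film_dose <- function(film_tbl, calibration) {
  need <- c("patient_id", "position", "pv_exposed", "pv_unexposed")
  if (!all(need %in% names(film_tbl))) {
    abort(sprintf("`film_tbl` must have columns %s",
                  paste(need, collapse = ", ")))
  }
  if (!all(film_tbl$position %in% c("medial", "lateral", "central"))) {
    abort("`position` must be medial, lateral or central")
  }
  film_tbl |>
    dplyr::mutate(net_od = net_od(.data$pv_exposed, .data$pv_unexposed),
                  dose_gy = predict(calibration, .data$net_od))
}

#' Per-patient surface-dose summary
#'
#' Arithmetic mean and SD of the calibrated dose per film position and
#' pooled over positions — the three-position skin-dose summary fed into
#' the dose-versus-toxicity correlation.
#'
#' @param dose_tbl Output of [film_dose()] (needs `patient_id`, `position`,
#'   `dose_gy`).
#' @return Tibble: `patient_id`, `position` (including `"overall"`),
#'   `mean_dose_gy`, `sd_dose_gy` (`NA` for single measurements), `n`.
#' @export
patient_surface_dose <- function(dose_tbl) {
  need <- c("patient_id", "position", "dose_gy")
  if (!all(need %in% names(dose_tbl)) || nrow(dose_tbl) == 0L) {
    abort("`dose_tbl` must be nonempty with patient_id, position, dose_gy")
  }
  per_pos <- dose_tbl |>
    dplyr::group_by(.data$patient_id, .data$position) |>
    dplyr::summarise(mean_dose_gy = mean(.data$dose_gy),
                     sd_dose_gy = ifelse(dplyr::n() > 1, sd(.data$dose_gy),
                                         NA_real_),
                     n = dplyr::n(), .groups = "drop")
  overall <- dose_tbl |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(position = "overall", mean_dose_gy = mean(.data$dose_gy),
                     sd_dose_gy = ifelse(dplyr::n() > 1, sd(.data$dose_gy),
                                         NA_real_),
                     n = dplyr::n(), .groups = "drop")
  dplyr::bind_rows(per_pos, overall) |>
    dplyr::arrange(.data$patient_id, .data$position)
}
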
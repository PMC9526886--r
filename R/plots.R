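# ggplot2 views of the main result types.

#' Plot per-patient and cohort dose-response curves
#'
#' Control-subtracted 30-min geometric mean versus dose, one thin line per
#' patient, with the cohort mean overlaid — the visual counterpart of the
#' per-patient slope index.
#'
#' @inheritParams irs_index_table
#' @param time Induction timepoint (h).
#' @return A ggplot object.
#' @export
plot_dose_response <- function(gm_tbl, time = 0.5) {
  df <- gm_tbl |>
    dplyr::filter(.data$time_h == time) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(gm_norm = .data$gm - .data$gm[.data$dose_gy == 0]) |>
    dplyr::ungroup()
  mean_df <- df |>
    dplyr::group_by(.data$dose_gy) |>
    dplyr::summarise(gm_norm = mean(.data$gm_norm), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$dose_gy, .data$gm_norm)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$patient_id),
                       alpha = 0.3, linewidth = 0.3) +
    ggplot2::geom_line(data = mean_df, colour = "red", linewidth = 1) +
    ggplot2::geom_point(data = mean_df, colour = "red", size = 2) +
    ggplot2::labs(x = "Dose (Gy)",
                  y = "Geometric mean γH2AX (control-subtracted)",
                  title = "Per-patient dose-response") +
    ggplot2::theme_minimal()
}

#' Heat map of induction indices and toxicity grade
#'
#' @param index_tbl Output of [irs_index_table()] with `rtog_grade`.
#' @return A ggplot object (tiles: patients x index columns, fill scaled
#'   within column; grade shown as its own column).
#' @export
plot_index_heatmap <- function(index_tbl) {
  hm <- heatmap_matrix(index_tbl)
  long <- hm |>
    tidyr::pivot_longer(-"patient_id", names_to = "index",
                        values_to = "value") |>
    dplyr::group_by(.data$index) |>
    dplyr::mutate(scaled = (.data$value - min(.data$value)) /
                    max(diff(range(.data$value)), .Machine$double.eps)) |>
    dplyr::ungroup()
  ggplot2::ggplot(long, ggplot2::aes(.data$index, .data$patient_id,
                                     fill = .data$scaled)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "scaled\nvalue") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "DSB induction and RTOG grade by patient") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 5))
}

#' @describeIn roc_analysis ROC curve with the Youden-optimal point marked.
#' @param object An `irs_roc`.
#' @param ... Unused.
#' @method autoplot irs_roc
#' @export
autoplot.irs_roc <- function(object, ...) {
  opt <- tibble::tibble(fpr = 1 - object$optimal_specificity,
                        sensitivity = object$optimal_sensitivity)
  ggplot2::ggplot(object$points,
                  ggplot2::aes(.data$fpr, .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::geom_point(data = opt, colour = "red", size = 2.5) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("ROC (AUC = %.3f, Youden cutoff = %.3g)",
                                  object$auc, object$optimal_cutoff)) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_calibration Calibration curve over its fit domain.
#' @param object A `film_calibration`.
#' @param ... Unused.
#' @method autoplot film_calibration
#' @export
autoplot.film_calibration <- function(object, ...) {
  grid <- tibble::tibble(
    net_od = seq(object$domain[1], object$domain[2], length.out = 200))
  grid$dose_gy <- predict(object, grid$net_od)
  ggplot2::ggplot(grid, ggplot2::aes(.data$net_od, .data$dose_gy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "net optical density", y = "Dose (Gy)",
                  title = sprintf("dose = %.3g netOD + %.3g netOD^%.3g",
                                  object$a, object$b, object$n)) +
    ggplot2::theme_minimal()
}
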
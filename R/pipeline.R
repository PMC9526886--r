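# End-to-end orchestration: cohort (simulated or read from disk) ->
# geometric means -> indices -> correlations, thresholds, classifiers, ROC
# -> serialized report.

#' Prevalence of overreactors in a grade vector
#'
#' @param grades RTOG-style ordinal grades, integers 0-4.
#' @param positive_grade Minimum grade counting as an overreactor.
#' @return One-row tibble: `n`, `n_positive`, `pct_grade_ge2`,
#'   `pct_grade_0_1` (the complement below grade 2; when `positive_grade`
#'   differs from 2 the two columns still partition at `positive_grade`).
#' @examples
#' grade_prevalence(rep(0:4, c(0, 32, 14, 4, 0))) # 36% / 64%
#' @export
grade_prevalence <- function(grades, positive_grade = 2) {
  assert_numeric_vec(grades, "grades")
  if (any(grades != round(grades)) || any(grades < 0 | grades > 4)) {
    abort("grades must be integers in 0..4")
  }
  n <- length(grades)
  npos <- sum(grades >= positive_grade)
  tibble::tibble(n = n, n_positive = npos,
                 pct_grade_ge2 = 100 * npos / n,
                 pct_grade_0_1 = 100 * (n - npos) / n)
}

index_columns <- function(reporting_dose, residual_times = c(3, 24)) {
  c(sprintf("dsb_%sgy", num_label(reporting_dose)),
    sprintf("residual%sh_pct", num_label(residual_times)),
    "slope")
}

#' Run the full radiosensitivity study pipeline
#'
#' Executes the stages in fixed order: obtain a cohort (simulate from
#' `config`, or read event files and metadata from `events_dir`), compute
#' gated per-sample geometric means, build the per-patient index table,
#' then the statistical layer — cohort dose-response linearity, one-way
#' ANOVA across doses, normality of each index, Pearson correlations of
#' each index (and mean surface dose) with toxicity grade, Gaussian-centile
#' threshold classifiers at the 68th and 95th centiles, and ROC analysis
#' with the Youden-optimal cutoff. Identical `config` + seed gives
#' byte-identical outputs.
#'
#' If every patient falls on one side of `positive_grade` the classifier and
#' ROC stages are skipped with a message and the rest of the report
#' completes.
#'
#' @param config A [cohort_config()] (simulation mode). Exactly one of
#'   `config` / `events_dir` must be supplied.
#' @param events_dir Directory of event files plus `cohort_metadata.csv`
#'   (analysis mode, see [write_cohort()]).
#' @param gate A [gate_spec()] applied before geometric means.
#' @param reporting_dose Dose (Gy) for the induction/residual indices.
#' @param k_values Centile multipliers for the threshold rules.
#' @param positive_grade Minimum grade defining the positive class.
#' @param bootstrap_reps If > 0, bootstrap replicates for AUC confidence
#'   intervals.
#' @param seed Seed for the bootstrap stage; defaults to `config$seed` (1 in
#'   analysis mode).
#' @param out_dir If non-`NULL`, write `indices.csv`, `correlations.csv`,
#'   `classifier.json`, `roc_<index>.csv` and `report.md` there.
#' @return An `irs_report` list: `$cohort_summary`, `$gm_table`,
#'   `$index_table`, `$dose_response` ([cohort_dose_response()]), `$anova`,
#'   `$normality`, `$correlations`, `$thresholds`, `$classifiers`, `$roc`,
#'   `$auc_ci`, `$provenance`.
#' @export
run_study <- function(config = NULL, events_dir = NULL,
                      gate = gate_spec("none"), reporting_dose = 2,
                      k_values = c(1, 2), positive_grade = 2,
                      bootstrap_reps = 0, seed = NULL, out_dir = NULL) {
  if (is.null(config) == is.null(events_dir)) {
    abort("supply exactly one of `config` or `events_dir`")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage `%s`: %s", name, conditionMessage(e)), parent = e)
    })
  }

  if (!is.null(config)) {
    patients <- stage("simulate", simulate_patients(config))
    gm_tbl <- stage("geometric_means", simulate_gm_table(config, gate))
    seed <- seed %||% config$seed
  } else {
    cohort <- stage("read", read_cohort(events_dir))
    patients <- cohort$patients
    gm_tbl <- stage("geometric_means", summarise_gm(cohort$events, gate))
    seed <- seed %||% 1L
  }
  meta <- dplyr::select(patients, "patient_id", "rtog_grade",
                        dplyr::any_of(c("dose_medial_gy", "dose_lateral_gy",
                                        "dose_central_gy")))
  index_tbl <- stage("indices",
                     irs_index_table(gm_tbl, meta = meta,
                                     reporting_dose = reporting_dose))
  grades <- index_tbl$rtog_grade
  prev <- grade_prevalence(grades, positive_grade)
  grade_counts <- index_tbl |>
    dplyr::count(.data$rtog_grade, name = "n_patients")

  dr <- stage("dose_response", cohort_dose_response(gm_tbl))
  anova_tbl <- stage("anova", anova_across_doses(gm_tbl))

  idx_cols <- index_columns(reporting_dose)
  idx_cols <- idx_cols[idx_cols %in% names(index_tbl)]

  normality <- purrr::map(idx_cols, function(col) {
    v <- index_tbl[[col]]
    tryCatch(dplyr::mutate(ks_normality(v[is.finite(v)]), index_name = col,
                           .before = 1),
             error = function(e) NULL)
  }) |> dplyr::bind_rows()

  surface <- NULL
  if (all(c("dose_medial_gy", "dose_lateral_gy", "dose_central_gy") %in%
          names(index_tbl))) {
    surface <- rowMeans(index_tbl[, c("dose_medial_gy", "dose_lateral_gy",
                                      "dose_central_gy")])
  }
  corr_inputs <- c(
    setNames(purrr::map(idx_cols, ~ index_tbl[[.x]]), idx_cols),
    if (!is.null(surface)) list(surface_dose = surface)
  )
  correlations <- purrr::imap(corr_inputs, function(v, nm) {
    tryCatch(pearson_cor(v, grades, index_name = nm),
             error = function(e) NULL)
  }) |> dplyr::bind_rows()

  single_class <- all(grades >= positive_grade) ||
    !any(grades >= positive_grade)
  thresholds <- list(); classifiers <- list(); roc <- list(); auc_ci <- NULL
  if (single_class) {
    inform("single-class truth: classifier and ROC stages skipped")
  } else {
    for (col in idx_cols) {
      v <- index_tbl[[col]]
      for (k in k_values) {
        rule <- gaussian_threshold(v, k = k, direction = "high_is_sensitive",
                                   index_name = col)
        key <- sprintf("%s_k%d", col, k)
        thresholds[[key]] <- rule
        classifiers[[key]] <- classify_and_score(v, grades, rule,
                                                 positive_grade)
      }
      roc[[col]] <- roc_analysis(v[is.finite(v)],
                                 grades[is.finite(v)] >= positive_grade,
                                 direction = "high")
    }
    if (bootstrap_reps > 0) {
      auc_ci <- purrr::imap(corr_inputs[idx_cols], function(v, nm) {
        ok <- is.finite(v)
        dplyr::mutate(
          roc_auc_ci(v[ok], grades[ok] >= positive_grade,
                     reps = bootstrap_reps, seed = seed),
          index_name = nm, .before = 1)
      }) |> dplyr::bind_rows()
    }
  }

  report <- structure(list(
    cohort_summary = list(n = nrow(index_tbl), grade_counts = grade_counts,
                          prevalence = prev),
    gm_table = gm_tbl, index_table = index_tbl, dose_response = dr,
    anova = anova_tbl, normality = normality, correlations = correlations,
    thresholds = thresholds, classifiers = classifiers, roc = roc,
    auc_ci = auc_ci,
    provenance = list(
      seed = seed, reporting_dose = reporting_dose,
      positive_grade = positive_grade, single_class = single_class,
      config_hash = rlang::hash(config),
      package_version = as.character(utils::packageVersion("radsens")))
  ), class = "irs_report")

  if (!is.null(out_dir)) write_report_files(report, out_dir)
  report
}

#' @export
print.irs_report <- function(x, ...) {
  cs <- x$cohort_summary
  cat(sprintf("<irs_report> %d patients; %.1f%% grade >= %d\n",
              cs$n, cs$prevalence$pct_grade_ge2, x$provenance$positive_grade))
  cat(sprintf("  cohort dose-response: slope %.2f, r2 %.4f; ANOVA p = %.3g\n",
              x$dose_response$slope, x$dose_response$r2,
              x$anova$p_value))
  if (nrow(x$correlations)) {
    cat("  Pearson r vs grade:\n")
    for (i in seq_len(nrow(x$correlations))) {
      cat(sprintf("    %-18s r = %+.3f (p = %.2g, n = %d)\n",
                  x$correlations$index_name[i], x$correlations$r[i],
                  x$correlations$p_value[i], x$correlations$n_used[i]))
    }
  }
  if (length(x$roc)) {
    cat("  ROC AUC (Youden cutoff):\n")
    for (nm in names(x$roc)) {
      r <- x$roc[[nm]]
      cat(sprintf("    %-18s AUC = %.3f, cutoff = %.3g\n", nm, r$auc,
                  r$optimal_cutoff))
    }
  }
  invisible(x)
}

# Deterministic serialisation of a report (no timestamps) so identical
# config + seed produce byte-identical artifacts.
write_report_files <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$index_table, file.path(out_dir, "indices.csv"))
  readr::write_csv(report$correlations, file.path(out_dir, "correlations.csv"))
  cls <- purrr::map(report$classifiers, function(cl) {
    as.list(glance(cl))
  })
  jsonlite::write_json(cls, file.path(out_dir, "classifier.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in names(report$roc)) {
    readr::write_csv(
      dplyr::select(report$roc[[nm]]$points, "fpr", "sensitivity",
                    "threshold"),
      file.path(out_dir, sprintf("roc_%s.csv", nm)))
  }
  writeLines(report_markdown(report), file.path(out_dir, "report.md"))
  invisible(out_dir)
}

report_markdown <- function(x) {
  cs <- x$cohort_summary
  lines <- c(
    "# Intrinsic radiosensitivity study report", "",
    sprintf("- Patients: %d", cs$n),
    sprintf("- Grade >= %d: %.1f%% (grades below: %.1f%%)",
            x$provenance$positive_grade, cs$prevalence$pct_grade_ge2,
            cs$prevalence$pct_grade_0_1),
    sprintf("- Cohort dose-response: slope %.3f GM units/Gy, r2 %.4f",
            x$dose_response$slope, x$dose_response$r2),
    sprintf("- ANOVA across doses: F = %.2f, p = %.3g",
            x$anova$f_statistic, x$anova$p_value),
    "", "## Correlations with RTOG grade", "",
    "| index | r | p | n |", "|---|---|---|---|")
  for (i in seq_len(nrow(x$correlations))) {
    lines <- c(lines, sprintf(
      "| %s | %.3f | %.3g | %d |", x$correlations$index_name[i],
      x$correlations$r[i], x$correlations$p_value[i],
      x$correlations$n_used[i]))
  }
  if (length(x$roc)) {
    lines <- c(lines, "", "## ROC", "",
               "| index | AUC | Youden cutoff | sens % | spec % |",
               "|---|---|---|---|---|")
    for (nm in names(x$roc)) {
      r <- x$roc[[nm]]
      lines <- c(lines, sprintf(
        "| %s | %.3f | %.4g | %.1f | %.1f |", nm, r$auc, r$optimal_cutoff,
        100 * r$optimal_sensitivity, 100 * r$optimal_specificity))
    }
  }
  c(lines, "",
    sprintf("Seed %s; config hash %s; radsens %s", x$provenance$seed,
            x$provenance$config_hash, x$provenance$package_version))
}
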
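# Event-level cytometry: reading samples, scatter gating, and the geometric
# mean fluorescence statistic that every radiosensitivity index consumes.

# Map channel names found in a file to the roles the pipeline needs.
# An explicit `channels` mapping always wins; otherwise fall back to the
# usual cytometer naming patterns. Ambiguity is an error, never a guess.
resolve_channels <- function(names, channels = NULL) {
  roles <- c(scatter1 = "^FSC", scatter2 = "^SSC",
             gamma_h2ax = "^(FITC|FL1)", dna = "^(PI|FL2|FL3)")
  out <- list()
  for (role in names(roles)) {
    if (!is.null(channels) && !is.null(channels[[role]])) {
      nm <- channels[[role]]
      if (!nm %in% names) {
        abort(sprintf("channel `%s` (role %s) not present in: %s",
                      nm, role, paste(names, collapse = ", ")))
      }
      out[[role]] <- nm
      next
    }
    hits <- grep(roles[[role]], names, value = TRUE, ignore.case = TRUE)
    if (length(hits) > 1L) {
      abort(sprintf("ambiguous channels for role %s: %s; supply `channels`.",
                    role, paste(hits, collapse = ", ")))
    }
    if (length(hits) == 1L) out[[role]] <- hits
  }
  if (is.null(out$gamma_h2ax)) {
    abort(sprintf("no channel resolvable to the gamma-H2AX role in: %s",
                  paste(names, collapse = ", ")))
  }
  unlist(out)
}

# Parse `P01_2Gy_0.5h.csv`-style names into (patient_id, dose_gy, time_h).
parse_sample_filename <- function(path) {
  base <- sub("\\.(csv|fcs)$", "", basename(path), ignore.case = TRUE)
  m <- regmatches(base, regexec("^(.+)_([0-9.]+)Gy_([0-9.]+)h$", base))[[1]]
  if (length(m) != 4L) {
    return(list(patient_id = base, dose_gy = NA_real_, time_h = NA_real_))
  }
  list(patient_id = m[2], dose_gy = as.numeric(m[3]), time_h = as.numeric(m[4]))
}

#' Read one event-level cytometry sample
#'
#' Reads a single tube's per-event measurements from either the plain-text
#' event-table dialect (CSV with header `FSC,SSC,FITC,PI`, one event per row)
#' or an FCS 3.0/3.1 list-mode file. Patient id, absorbed dose and
#' post-irradiation timepoint are recovered from the file name
#' (`{patient}_{dose}Gy_{time}h.{csv|fcs}`) unless supplied explicitly.
#'
#' @param path Path to the sample file.
#' @param format `"auto"` (by extension), `"csv"` or `"fcs"`.
#' @param channels Optional named list/vector mapping the roles
#'   `scatter1`, `scatter2`, `gamma_h2ax`, `dna` to channel names in the file;
#'   when omitted, standard name patterns (`FSC*`, `SSC*`, `FITC*`/`FL1`,
#'   `PI*`/`FL2`) are used and any ambiguity is an error.
#' @param patient_id,dose_gy,time_h Optional metadata overriding the filename.
#'
#' @return A tibble with one row per event, in file order: `patient_id`,
#'   `dose_gy`, `time_h` plus the file's channel columns. The resolved
#'   channel-role mapping is attached as attribute `"channels"` and the source
#'   path as `"source"`.
#' @examples
#' f <- tempfile("P01_2Gy_0.5h", fileext = ".csv")
#' writeLines(c("FSC,SSC,FITC,PI", "400,200,35,150", "410,190,40,160"), f)
#' read_events(f)
#' @export
read_events <- function(path, format = c("auto", "csv", "fcs"),
                        channels = NULL, patient_id = NULL, dose_gy = NULL,
                        time_h = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "csv"
  }
  events <- if (format == "fcs") {
    read_fcs(path)
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  if (nrow(events) == 0L) abort(sprintf("zero events in %s", path))
  ch <- resolve_channels(names(events), channels)
  meta <- parse_sample_filename(path)
  out <- dplyr::bind_cols(
    tibble::tibble(
      patient_id = patient_id %||% meta$patient_id,
      dose_gy = dose_gy %||% meta$dose_gy,
      time_h = time_h %||% meta$time_h
    ),
    tibble::as_tibble(events)
  )
  attr(out, "channels") <- ch
  attr(out, "source") <- path
  out
}

#' Specify a lymphocyte scatter gate
#'
#' Declarative replacement for an interactive gating step: a region on the
#' two scatter channels that keeps intact lymphocytes and drops debris.
#' `mode = "none"` is the identity gate (the default, appropriate for clean
#' synthetic data). `"rectangle"` keeps events with both scatter values inside
#' the given ranges; `"ellipse"` keeps events inside the axis-aligned ellipse
#' inscribed in that rectangle.
#'
#' @param mode `"none"`, `"rectangle"` or `"ellipse"`.
#' @param scatter1_range,scatter2_range Length-2 ascending numeric bounds on
#'   the forward and side scatter channels; required unless `mode = "none"`.
#' @param min_events_after_gate Minimum events that must survive the gate.
#' @return A `gate_spec` object.
#' @export
gate_spec <- function(mode = c("none", "rectangle", "ellipse"),
                      scatter1_range = NULL, scatter2_range = NULL,
                      min_events_after_gate = 1L) {
  mode <- match.arg(mode)
  min_events_after_gate <- assert_count(min_events_after_gate,
                                        "min_events_after_gate")
  if (mode != "none") {
    for (nm in c("scatter1_range", "scatter2_range")) {
      r <- get(nm)
      if (is.null(r) || length(r) != 2L || !all(is.finite(r)) || r[1] >= r[2]) {
        abort(sprintf("`%s` must be finite ascending bounds when mode != 'none'.",
                      nm))
      }
    }
  }
  structure(list(mode = mode, scatter1_range = scatter1_range,
                 scatter2_range = scatter2_range,
                 min_events_after_gate = min_events_after_gate),
            class = "gate_spec")
}

#' @export
print.gate_spec <- function(x, ...) {
  if (x$mode == "none") {
    cat("<gate_spec> none (identity)\n")
  } else {
    cat(sprintf("<gate_spec> %s: scatter1 [%g, %g], scatter2 [%g, %g]\n",
                x$mode, x$scatter1_range[1], x$scatter1_range[2],
                x$scatter2_range[1], x$scatter2_range[2]))
  }
  invisible(x)
}

#' Apply a scatter gate to an event table
#'
#' @param events Event tibble as returned by [read_events()] or found in
#'   [simulate_cohort()]'s `$events` (any extra columns are carried through).
#' @param gate A [gate_spec()].
#' @param channels Optional explicit channel-role mapping (see
#'   [read_events()]).
#' @return The gated event tibble (a subset of rows, order preserved).
#' @export
apply_gate <- function(events, gate = gate_spec("none"), channels = NULL) {
  stopifnot(inherits(gate, "gate_spec"))
  if (gate$mode == "none") {
    if (nrow(events) < gate$min_events_after_gate) {
      abort("fewer events than `min_events_after_gate`")
    }
    return(events)
  }
  ch <- resolve_channels(names(events), channels)
  if (!all(c("scatter1", "scatter2") %in% names(ch))) {
    abort("gating requires resolvable scatter channels")
  }
  x <- events[[ch[["scatter1"]]]]
  y <- events[[ch[["scatter2"]]]]
  keep <- if (gate$mode == "rectangle") {
    x >= gate$scatter1_range[1] & x <= gate$scatter1_range[2] &
      y >= gate$scatter2_range[1] & y <= gate$scatter2_range[2]
  } else {
    cx <- mean(gate$scatter1_range); rx <- diff(gate$scatter1_range) / 2
    cy <- mean(gate$scatter2_range); ry <- diff(gate$scatter2_range) / 2
    ((x - cx) / rx)^2 + ((y - cy) / ry)^2 <= 1
  }
  out <- events[keep, , drop = FALSE]
  if (nrow(out) == 0L) abort("gate excludes every event")
  if (nrow(out) < gate$min_events_after_gate) {
    abort(sprintf("only %d events after gating (< min_events_after_gate = %d)",
                  nrow(out), gate$min_events_after_gate))
  }
  out
}

#' Geometric mean fluorescence intensity
#'
#' The standard flow-cytometry location statistic for log-normally
#' distributed signals: `exp(mean(log(x)))` over the usable intensities.
#' Nonpositive values (possible after instrument compensation) are handled by
#' policy: `"exclude"` drops them and records how many were dropped in the
#' `"n_excluded"` attribute of the result; `"shift_epsilon"` translates the
#' whole vector so its minimum becomes `epsilon` before averaging (intended
#' for small fixtures, not production data).
#'
#' @param x Numeric vector of per-event intensities.
#' @param nonpositive `"exclude"` or `"shift_epsilon"`.
#' @param epsilon Positive shift target used by `"shift_epsilon"`.
#' @return Scalar geometric mean with attribute `n_excluded`.
#' @examples
#' geometric_mean(c(1, 10, 100)) # 10
#' @export
geometric_mean <- function(x, nonpositive = c("exclude", "shift_epsilon"),
                           epsilon = 1e-6) {
  nonpositive <- match.arg(nonpositive)
  if (!is.numeric(x) || length(x) == 0L) {
    abort("`x` must be a non-empty numeric vector.")
  }
  x <- x[!is.na(x)]
  n_excluded <- 0L
  if (nonpositive == "exclude") {
    usable <- x[x > 0]
    n_excluded <- length(x) - length(usable)
  } else {
    assert_number(epsilon, "epsilon", positive = TRUE)
    if (length(x) && min(x) <= 0) x <- x + (epsilon - min(x))
    usable <- x
  }
  if (length(usable) == 0L) abort("no usable (positive) intensities")
  structure(exp(mean(log(usable))), n_excluded = n_excluded)
}

#' Per-sample gated geometric means
#'
#' Groups an event table by sample (`patient_id`, `dose_gy`, `time_h`),
#' applies the gate, and computes the geometric mean of the gamma-H2AX
#' channel — the per-sample summary all downstream indices are built on.
#'
#' @inheritParams apply_gate
#' @param nonpositive Policy for nonpositive intensities, see
#'   [geometric_mean()].
#' @return A tibble with one row per sample: `patient_id`, `dose_gy`,
#'   `time_h`, `n_events_total`, `n_events_gated`, `n_excluded_nonpositive`,
#'   `gm`.
#' @export
summarise_gm <- function(events, gate = gate_spec("none"), channels = NULL,
                         nonpositive = "exclude") {
  ch <- resolve_channels(names(events), channels)
  signal <- ch[["gamma_h2ax"]]
  events |>
    dplyr::group_by(.data$patient_id, .data$dose_gy, .data$time_h) |>
    dplyr::group_modify(function(df, key) {
      gated <- apply_gate(df, gate, channels = channels)
      gm <- geometric_mean(gated[[signal]], nonpositive = nonpositive)
      tibble::tibble(
        n_events_total = nrow(df),
        n_events_gated = nrow(gated),
        n_excluded_nonpositive = attr(gm, "n_excluded"),
        gm = as.numeric(gm)
      )
    }) |>
    dplyr::ungroup()
}
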
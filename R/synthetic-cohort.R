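# Synthetic patient cohorts with event-level cytometry data.
#
# The generator encodes the statistical structure the analysis assumes:
# per-event gamma-H2AX fluorescence is log-normal; its geometric mean rises
# linearly with dose at the 30-min induction timepoint with a patient-specific
# slope (the latent radiosensitivity); damage decays exponentially with a
# patient-specific repair half-life; an ordinal skin-toxicity grade is coupled
# to the latent sensitivity through cutpoints; and in-vivo surface doses are
# drawn independently of grade.

#' Configuration for a synthetic cohort
#'
#' All downstream behaviour of [simulate_cohort()] is determined by this
#' object plus its `seed`; the same configuration always reproduces the same
#' cohort bit-for-bit.
#'
#' The generative model per patient \eqn{p}, dose \eqn{D} and time \eqn{t}:
#' per-event intensity is log-normal with geometric mean
#' \deqn{GM(p, D, t) = baseline(p) + sensitivity(p) \cdot D \cdot \rho(t)}
#' where \eqn{\rho(t) = 1} at the induction timepoint (0.5 h) and
#' \eqn{\rho(t) = 2^{-(t - 0.5)/halflife(p)}} later. The RTOG-style grade is
#' the number of `grade_cutpoints` below `sensitivity + noise`; repair
#' half-life is correlated with sensitivity through a Gaussian copula
#' (`repair_coupling`), so poor repairers tend to be the clinically sensitive
#' patients.
#'
#' @param n_patients Number of patients.
#' @param doses Absorbed doses in Gy; must be sorted, nonnegative and include
#'   the unirradiated control (0).
#' @param timepoints Hours post-irradiation, sorted and positive. The first
#'   is treated as the induction timepoint where \eqn{\rho = 1}.
#' @param events_per_sample Events recorded per tube.
#' @param seed Integer seed; every random draw derives from it.
#' @param induction_slope_mean,induction_slope_sd Mean/SD of the latent
#'   per-patient induction slope (geometric-mean fluorescence units per Gy).
#' @param baseline_gm_mean,baseline_gm_sd Mean/SD of the unirradiated
#'   geometric mean (fluorescence units).
#' @param repair_halflife_mean,repair_halflife_sd Mean/SD of the repair
#'   half-life in hours.
#' @param repair_coupling Correlation (on the latent normal scale) between
#'   induction slope and repair half-life; positive means sensitive patients
#'   repair more slowly.
#' @param grade_cutpoints Four strictly increasing latent-scale values mapping
#'   sensitivity to grades 0-4. Defaults are calibrated so that, under the
#'   default generator parameters, roughly 64% of patients land in grades 0-1,
#'   28% in grade 2 and 8% in grade 3, with grades 0 and 4 rare.
#' @param grade_noise_sd SD of ordinal noise added to the latent sensitivity
#'   before applying the cutpoints (0 = deterministic coupling).
#' @param couple_grade If `FALSE`, the grade is driven by an independent
#'   latent draw, severing the sensitivity-grade link (null cohorts).
#' @param event_cv Coefficient of variation of per-event intensity around its
#'   geometric mean; 0 gives the exact noise-free limit.
#' @param debris_fraction Expected fraction of low-scatter debris events per
#'   tube (they carry only autofluorescence on the gamma-H2AX channel).
#' @param surface_dose_range Uniform range (Gy) for the three per-patient
#'   film surface doses, drawn independently of grade.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 50L,
                          doses = c(0, 1, 2),
                          timepoints = c(0.5, 3, 24),
                          events_per_sample = 10000L,
                          seed = 1L,
                          induction_slope_mean = 15,
                          induction_slope_sd = 7,
                          baseline_gm_mean = 20,
                          baseline_gm_sd = 3,
                          repair_halflife_mean = 5,
                          repair_halflife_sd = 2,
                          repair_coupling = 0.6,
                          grade_cutpoints = c(0.5, 18.1, 27.1, 60),
                          grade_noise_sd = 5,
                          couple_grade = TRUE,
                          event_cv = 0.8,
                          debris_fraction = 0.05,
                          surface_dose_range = c(0.92, 1.9)) {
  n_patients <- assert_count(n_patients, "n_patients")
  events_per_sample <- assert_count(events_per_sample, "events_per_sample")
  seed <- assert_count(seed, "seed", min = 0L)
  assert_numeric_vec(doses, "doses", min_len = 1L)
  if (is.unsorted(doses, strictly = TRUE) || any(doses < 0) || !0 %in% doses) {
    abort("`doses` must be strictly increasing, nonnegative, and include 0.")
  }
  assert_numeric_vec(timepoints, "timepoints")
  if (is.unsorted(timepoints, strictly = TRUE) || any(timepoints <= 0)) {
    abort("`timepoints` must be strictly increasing and positive.")
  }
  assert_numeric_vec(grade_cutpoints, "grade_cutpoints", min_len = 4L)
  if (length(grade_cutpoints) != 4L ||
      is.unsorted(grade_cutpoints, strictly = TRUE)) {
    abort("`grade_cutpoints` must be 4 strictly increasing values.")
  }
  for (nm in c("induction_slope_mean", "baseline_gm_mean",
               "repair_halflife_mean")) {
    assert_number(get(nm), nm, positive = TRUE)
  }
  for (nm in c("induction_slope_sd", "baseline_gm_sd", "repair_halflife_sd",
               "grade_noise_sd", "event_cv", "debris_fraction")) {
    assert_number(get(nm), nm, nonnegative = TRUE)
  }
  if (debris_fraction >= 1) abort("`debris_fraction` must be < 1.")
  assert_number(repair_coupling, "repair_coupling")
  if (abs(repair_coupling) > 1) abort("`repair_coupling` must be in [-1, 1].")
  assert_numeric_vec(surface_dose_range, "surface_dose_range", min_len = 2L)
  if (length(surface_dose_range) != 2L || surface_dose_range[1] <= 0 ||
      surface_dose_range[1] > surface_dose_range[2]) {
    abort("`surface_dose_range` must be positive ascending (lo, hi).")
  }
  structure(
    list(n_patients = n_patients, doses = doses, timepoints = timepoints,
         events_per_sample = events_per_sample, seed = seed,
         induction_slope_mean = induction_slope_mean,
         induction_slope_sd = induction_slope_sd,
         baseline_gm_mean = baseline_gm_mean,
         baseline_gm_sd = baseline_gm_sd,
         repair_halflife_mean = repair_halflife_mean,
         repair_halflife_sd = repair_halflife_sd,
         repair_coupling = repair_coupling,
         grade_cutpoints = grade_cutpoints,
         grade_noise_sd = grade_noise_sd, couple_grade = couple_grade,
         event_cv = event_cv, debris_fraction = debris_fraction,
         surface_dose_range = surface_dose_range),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<cohort_config> %d patients, doses {%s} Gy, timepoints {%s} h, ",
    "%d events/sample, seed %d\n"),
    x$n_patients, paste(num_label(x$doses), collapse = ", "),
    paste(num_label(x$timepoints), collapse = ", "),
    x$events_per_sample, x$seed))
  invisible(x)
}

# Repair factor rho(t): fraction of the 30-min induction still present.
repair_fraction <- function(time_h, halflife_h, induction_time_h = 0.5) {
  ifelse(time_h <= induction_time_h, 1,
         2^(-(time_h - induction_time_h) / halflife_h))
}

# Generative geometric mean for one patient/dose/time cell.
generative_gm <- function(baseline_gm, sensitivity, dose_gy, time_h,
                          halflife_h, induction_time_h = 0.5) {
  baseline_gm + sensitivity * dose_gy *
    repair_fraction(time_h, halflife_h, induction_time_h)
}

draw_truncated_positive <- function(mean, sd, floor = 0) {
  if (sd == 0) return(max(mean, floor + .Machine$double.eps))
  for (i in 1:1000) {
    x <- rnorm(1, mean, sd)
    if (x > floor) return(x)
  }
  floor + sd * 1e-3
}

#' Draw the latent per-patient parameters of a cohort
#'
#' @param config A [cohort_config()].
#' @return Tibble with one row per patient: `patient_id`, `sensitivity`
#'   (induction slope, GM units/Gy), `baseline_gm`, `repair_halflife` (h),
#'   `rtog_grade` (0-4), `dose_medial_gy`, `dose_lateral_gy`,
#'   `dose_central_gy`.
#' @export
simulate_patients <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, {
    rows <- purrr::map(seq_len(config$n_patients), function(i) {
      baseline <- draw_truncated_positive(config$baseline_gm_mean,
                                          config$baseline_gm_sd)
      z_s <- 0
      if (config$induction_slope_sd == 0) {
        sens <- config$induction_slope_mean
      } else {
        repeat {
          z_s <- rnorm(1)
          sens <- config$induction_slope_mean +
            config$induction_slope_sd * z_s
          if (sens > 0) break
        }
      }
      rho <- config$repair_coupling
      hl <- NA_real_
      for (j in 1:100) {
        z_h <- rnorm(1)
        hl <- config$repair_halflife_mean + config$repair_halflife_sd *
          (rho * z_s + sqrt(1 - rho^2) * z_h)
        if (hl > 0.1) break
      }
      if (hl <= 0.1) hl <- 0.1
      g_latent <- if (config$couple_grade) sens else {
        config$induction_slope_mean + config$induction_slope_sd * rnorm(1)
      }
      g_latent <- g_latent + config$grade_noise_sd * rnorm(1)
      grade <- sum(config$grade_cutpoints < g_latent)
      sdose <- runif(3, config$surface_dose_range[1],
                     config$surface_dose_range[2])
      tibble::tibble(
        patient_id = sprintf("P%03d", i),
        sensitivity = sens, baseline_gm = baseline, repair_halflife = hl,
        rtog_grade = grade,
        dose_medial_gy = sdose[1], dose_lateral_gy = sdose[2],
        dose_central_gy = sdose[3]
      )
    })
    dplyr::bind_rows(rows)
  })
}

# Deterministic per-sample RNG seed so that full-cohort simulation and the
# streaming geometric-mean path generate identical events for each tube.
sample_seed <- function(seed, i, j, k) {
  as.integer((seed * 1000003 + i * 9973 + j * 97 + k) %% 2147483647)
}

# Scatter-cluster parameters for the lymphocyte population and low-scatter
# debris; fixed by design (the gate, not the clusters, is configurable).
LYMPH_FSC <- c(400, 50); LYMPH_SSC <- c(200, 40)
DEBRIS_FSC <- c(80, 30); DEBRIS_SSC <- c(60, 25)

sim_sample_events <- function(patient, dose_gy, time_h, config,
                              keep_membership = FALSE) {
  n <- config$events_per_sample
  gm <- generative_gm(patient$baseline_gm, patient$sensitivity, dose_gy,
                      time_h, patient$repair_halflife,
                      induction_time_h = config$timepoints[1])
  sdlog <- sqrt(log1p(config$event_cv^2))
  if (config$debris_fraction > 0) {
    is_debris <- runif(n) < config$debris_fraction
    fsc <- ifelse(is_debris, rnorm(n, DEBRIS_FSC[1], DEBRIS_FSC[2]),
                  rnorm(n, LYMPH_FSC[1], LYMPH_FSC[2]))
    ssc <- ifelse(is_debris, rnorm(n, DEBRIS_SSC[1], DEBRIS_SSC[2]),
                  rnorm(n, LYMPH_SSC[1], LYMPH_SSC[2]))
    fitc <- ifelse(is_debris, exp(rnorm(n, log(2), 0.5)),
                   exp(rnorm(n, log(gm), sdlog)))
    pi_ch <- ifelse(is_debris, exp(rnorm(n, log(20), 0.5)),
                    exp(rnorm(n, log(200), 0.15)))
  } else {
    is_debris <- rep(FALSE, n)
    fsc <- rnorm(n, LYMPH_FSC[1], LYMPH_FSC[2])
    ssc <- rnorm(n, LYMPH_SSC[1], LYMPH_SSC[2])
    fitc <- exp(rnorm(n, log(gm), sdlog))
    pi_ch <- exp(rnorm(n, log(200), 0.15))
  }
  out <- tibble::tibble(
    patient_id = patient$patient_id, dose_gy = dose_gy, time_h = time_h,
    FSC = pmax(fsc, 0), SSC = pmax(ssc, 0), FITC = fitc, PI = pi_ch
  )
  if (keep_membership) out$.lymphocyte <- !is_debris
  out
}

sample_grid <- function(config) {
  tidyr::expand_grid(i = seq_len(config$n_patients),
                     j = seq_along(config$doses),
                     k = seq_along(config$timepoints))
}

#' Simulate a full synthetic cohort with event-level data
#'
#' Produces one event table per patient x dose x timepoint tube. The result
#' is reproducible bit-for-bit from `config$seed`; each tube uses its own
#' derived seed, so [simulate_gm_table()] regenerates identical events
#' without materialising the whole cohort.
#'
#' @param config A [cohort_config()].
#' @param keep_membership Keep the (normally unobservable) `.lymphocyte`
#'   indicator column marking which events belong to the lymphocyte cluster
#'   rather than debris; used to validate gating.
#' @return An `irs_cohort`: list with `$patients` ([simulate_patients()]
#'   output) and `$events`, a long tibble of per-event values with columns
#'   `patient_id`, `dose_gy`, `time_h`, `FSC`, `SSC`, `FITC`, `PI`.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_patients = 2,
#'                                         events_per_sample = 100))
#' dplyr::count(cohort$events, patient_id, dose_gy, time_h)
#' @export
simulate_cohort <- function(config, keep_membership = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  patients <- simulate_patients(config)
  grid <- sample_grid(config)
  events <- purrr::pmap(grid, function(i, j, k) {
    withr::with_seed(
      sample_seed(config$seed, i, j, k),
      sim_sample_events(patients[i, ], config$doses[j], config$timepoints[k],
                        config, keep_membership = keep_membership)
    )
  })
  structure(list(patients = patients, events = dplyr::bind_rows(events),
                 config = config),
            class = "irs_cohort")
}

#' @export
print.irs_cohort <- function(x, ...) {
  cat(sprintf("<irs_cohort> %d patients, %d samples, %d events\n",
              nrow(x$patients),
              nrow(dplyr::distinct(x$events, .data$patient_id, .data$dose_gy,
                                   .data$time_h)),
              nrow(x$events)))
  invisible(x)
}

#' Per-sample geometric means without materialising the event tables
#'
#' Generates each tube's events from its derived seed, gates, summarises and
#' discards them, producing exactly the table
#' `summarise_gm(simulate_cohort(config)$events, gate)` would give while
#' holding only one tube in memory — the practical route for large cohorts.
#'
#' @inheritParams simulate_cohort
#' @inheritParams summarise_gm
#' @return Tibble as from [summarise_gm()].
#' @export
simulate_gm_table <- function(config, gate = gate_spec("none"),
                              nonpositive = "exclude") {
  stopifnot(inherits(config, "cohort_config"))
  patients <- simulate_patients(config)
  grid <- sample_grid(config)
  rows <- purrr::pmap(grid, function(i, j, k) {
    ev <- withr::with_seed(
      sample_seed(config$seed, i, j, k),
      sim_sample_events(patients[i, ], config$doses[j], config$timepoints[k],
                        config)
    )
    gated <- apply_gate(ev, gate)
    gm <- geometric_mean(gated$FITC, nonpositive = nonpositive)
    tibble::tibble(
      patient_id = patients$patient_id[i],
      dose_gy = config$doses[j], time_h = config$timepoints[k],
      n_events_total = nrow(ev), n_events_gated = nrow(gated),
      n_excluded_nonpositive = attr(gm, "n_excluded"),
      gm = as.numeric(gm)
    )
  })
  dplyr::bind_rows(rows)
}

#' Write a cohort to disk as event tables plus metadata
#'
#' One CSV (or FCS) file per tube named `{patient}_{dose}Gy_{time}h.{ext}`
#' with channel columns `FSC,SSC,FITC,PI`, plus `cohort_metadata.csv` with
#' columns `patient_id,rtog_grade,dose_medial_gy,dose_lateral_gy,
#' dose_central_gy`.
#'
#' @param cohort An `irs_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param format `"csv"` or `"fcs"`.
#' @return Invisibly, a tibble listing the files written.
#' @export
write_cohort <- function(cohort, dir, format = c("csv", "fcs")) {
  format <- match.arg(format)
  stopifnot(inherits(cohort, "irs_cohort"))
  if (nrow(cohort$patients) == 0L) abort("empty patient list")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- dplyr::select(cohort$patients, "patient_id", "rtog_grade",
                        "dose_medial_gy", "dose_lateral_gy", "dose_central_gy")
  readr::write_csv(meta, file.path(dir, "cohort_metadata.csv"))
  groups <- cohort$events |>
    dplyr::group_by(.data$patient_id, .data$dose_gy, .data$time_h) |>
    dplyr::group_split()
  files <- purrr::map_chr(groups, function(df) {
    fn <- sprintf("%s_%sGy_%sh.%s", df$patient_id[1], num_label(df$dose_gy[1]),
                  num_label(df$time_h[1]), format)
    path <- file.path(dir, fn)
    chans <- dplyr::select(df, -"patient_id", -"dose_gy", -"time_h",
                           -dplyr::any_of(".lymphocyte"))
    if (format == "csv") readr::write_csv(chans, path) else write_fcs(chans, path)
    path
  })
  invisible(tibble::tibble(path = c(file.path(dir, "cohort_metadata.csv"),
                                    files)))
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing `cohort_metadata.csv` and per-tube event
#'   files.
#' @param format `"auto"`, `"csv"` or `"fcs"` (passed to [read_events()]).
#' @return An `irs_cohort` with `$patients` (the metadata table) and
#'   `$events`.
#' @export
read_cohort <- function(dir, format = "auto") {
  meta_path <- file.path(dir, "cohort_metadata.csv")
  if (!file.exists(meta_path)) {
    abort(sprintf("no cohort_metadata.csv in %s", dir))
  }
  patients <- readr::read_csv(meta_path, show_col_types = FALSE,
                              progress = FALSE)
  files <- list.files(dir, pattern = "_[0-9.]+Gy_[0-9.]+h\\.(csv|fcs)$",
                      full.names = TRUE)
  if (length(files) == 0L) abort(sprintf("no event files in %s", dir))
  events <- dplyr::bind_rows(purrr::map(files, read_events, format = format))
  structure(list(patients = patients, events = events, config = NULL),
            class = "irs_cohort")
}
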
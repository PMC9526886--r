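# Event reading, gating, and the geometric-mean statistic.

test_that("CSV event tables parse with filename metadata", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "P07_1Gy_3h.csv")
  writeLines(c("FSC,SSC,FITC,PI", "400,200,35,150", "410,190,40,160",
               "390,210,30,140"), f)
  ev <- read_events(f)
  expect_equal(nrow(ev), 3L)
  expect_equal(ev$patient_id[1], "P07")
  expect_equal(ev$dose_gy[1], 1)
  expect_equal(ev$time_h[1], 3)
  expect_equal(attr(ev, "channels")[["gamma_h2ax"]], "FITC")

  empty <- file.path(dir, "P07_0Gy_3h.csv")
  writeLines("FSC,SSC,FITC,PI", empty)
  expect_error(read_events(empty), "zero events")
})

test_that("FCS files written by write_fcs agree with their CSV twin", {
  co <- simulate_cohort(tiny_config())
  s <- dplyr::filter(co$events, patient_id == "P001", dose_gy == 2,
                     time_h == 0.5)
  dir <- withr::local_tempdir()
  fcs <- file.path(dir, "P001_2Gy_0.5h.fcs")
  csv <- file.path(dir, "P001_2Gy_0.5h.csv")
  write_fcs(s, fcs)
  readr::write_csv(dplyr::select(s, FSC, SSC, FITC, PI), csv)
  gm_fcs <- geometric_mean(read_events(fcs)$FITC)
  gm_csv <- geometric_mean(read_events(csv)$FITC)
  expect_lt(abs(gm_fcs - gm_csv) / gm_csv, 1e-6)
  expect_equal(names(read_events(fcs))[-(1:3)], c("FSC", "SSC", "FITC", "PI"))
})

test_that("channel-role ambiguity is an error, explicit mapping wins", {
  tbl <- tibble::tibble(FITC = 1:3, `FITC-H` = 1:3, FSC = 1, SSC = 1)
  expect_error(radsens:::resolve_channels(names(tbl)), "ambiguous")
  ch <- radsens:::resolve_channels(names(tbl), channels = list(gamma_h2ax = "FITC"))
  expect_equal(ch[["gamma_h2ax"]], "FITC")
  expect_error(radsens:::resolve_channels(c("A", "B")), "gamma-H2AX")
})

test_that("gating: identity, planted-membership recovery, and degenerates", {
  co <- simulate_cohort(tiny_config(debris_fraction = 0.2),
                       keep_membership = TRUE)
  s <- dplyr::filter(co$events, patient_id == "P001", dose_gy == 0,
                     time_h == 0.5)
  expect_identical(apply_gate(s, gate_spec("none")), s)

  g <- gate_spec("rectangle", scatter1_range = c(250, 600),
                 scatter2_range = c(80, 350))
  gated <- apply_gate(s, g)
  expect_identical(gated, s[s$.lymphocyte, ])
  expect_lte(nrow(gated), nrow(s))

  far <- gate_spec("rectangle", scatter1_range = c(1e5, 2e5),
                   scatter2_range = c(1e5, 2e5))
  expect_error(apply_gate(s, far), "excludes every event")
  expect_error(gate_spec("rectangle", scatter1_range = c(2, 1),
                         scatter2_range = c(0, 1)), "ascending")
})

test_that("ellipse gate is the inscribed ellipse of its bounding box", {
  ev <- tibble::tibble(FSC = c(400, 250, 400), SSC = c(200, 80, 70),
                       FITC = 1, PI = 1)
  g <- gate_spec("ellipse", scatter1_range = c(250, 550),
                 scatter2_range = c(80, 320))
  gated <- apply_gate(ev, g)
  # centre is inside; the two corner-ish points are outside the ellipse
  expect_equal(nrow(gated), 1L)
  expect_equal(gated$FSC, 400)
  expect_equal(gated$SSC, 200)
})

test_that("geometric mean matches frozen examples and handles nonpositives", {
  expect_equal(as.numeric(geometric_mean(rep(42, 10))), 42)
  expect_equal(as.numeric(geometric_mean(c(1, 10, 100))), 10)
  # independent log-sum oracle for {3, 7, 11}: 231^(1/3)
  expect_rel_equal(as.numeric(geometric_mean(c(3, 7, 11))), 231^(1 / 3),
                   tol = 1e-12)
  g <- geometric_mean(c(-1, 0, 2, 8))
  expect_equal(as.numeric(g), 4)
  expect_equal(attr(g, "n_excluded"), 2L)
  expect_error(geometric_mean(c(-1, 0)), "no usable")
  # shift is epsilon - min(x) = 2, mapping (-1, 0, 2) to (1, 2, 4)
  shifted <- geometric_mean(c(-1, 0, 2), nonpositive = "shift_epsilon",
                            epsilon = 1)
  expect_equal(as.numeric(shifted), gm_oracle(c(1, 2, 4)))
})

test_that("geometric mean is scale-equivariant, bounded, and oracle-exact", {
  set.seed(1)
  for (i in 1:200) {
    x <- exp(stats::rnorm(sample(2:50, 1), sd = 2))
    g <- as.numeric(geometric_mean(x))
    expect_rel_equal(g, gm_oracle(x))
    expect_gte(g, min(x) * (1 - 1e-12))
    expect_lte(g, max(x) * (1 + 1e-12))
    c0 <- stats::runif(1, 0.1, 10)
    expect_rel_equal(as.numeric(geometric_mean(c0 * x)), c0 * g)
  }
})

test_that("summarise_gm reports per-sample counts and gated statistics", {
  co <- simulate_cohort(tiny_config(debris_fraction = 0.2),
                       keep_membership = TRUE)
  g <- gate_spec("rectangle", scatter1_range = c(250, 600),
                 scatter2_range = c(80, 350))
  gm <- summarise_gm(co$events, gate = g)
  expect_equal(nrow(gm), 27L)
  expect_true(all(gm$n_events_gated <= gm$n_events_total))
  expect_true(all(gm$gm > 0))
  # gated GM at 2 Gy exceeds the ungated one (debris drags the GM down)
  gm_all <- summarise_gm(co$events)
  expect_true(all(gm$gm >= gm_all$gm))
})
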
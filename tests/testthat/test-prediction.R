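# Correlation, normality, Gaussian-centile thresholds, confusion metrics,
# ROC/AUC and ANOVA.

test_that("Pearson correlation matches the covariance-formula oracle", {
  x <- 1:10
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1)
  got <- pearson_cor(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_rel_equal(got$r, pearson_oracle(c(1, 2, 3, 4), c(2, 1, 4, 3)))
  expect_equal(got$r, 0.6)
  expect_equal(got$n_used, 4L)
  expect_error(pearson_cor(x, rep(1, 10)), "zero variance")
  expect_error(pearson_cor(1:2, 2:3), ">= 3")
  # two-sided p from the t transform, cross-checked on a random instance
  set.seed(4)
  x <- stats::rnorm(20); y <- x + stats::rnorm(20)
  got <- pearson_cor(x, y)
  r <- pearson_oracle(x, y)
  tt <- r * sqrt(18 / (1 - r^2))
  expect_rel_equal(got$p_value, 2 * stats::pt(-abs(tt), df = 18), tol = 1e-9)
})

test_that("KS normality accepts Gaussian data and flags bimodal data", {
  reps <- 100
  pass <- 0
  for (i in seq_len(reps)) {
    x <- withr::with_seed(1000 + i, stats::rnorm(10000, 50, 8))
    if (ks_normality(x)$p_value > 0.05) pass <- pass + 1
  }
  expect_gte(pass / reps, 0.9)

  gauss <- withr::with_seed(7, stats::rnorm(2000))
  bimod <- withr::with_seed(7, c(stats::rnorm(1000, -3), stats::rnorm(1000, 3)))
  expect_gt(ks_normality(bimod)$statistic, ks_normality(gauss)$statistic)
  expect_gt(ks_normality(gauss)$fit_r2, 0.9)
  expect_error(ks_normality(rep(1, 10)), "constant")
  expect_error(ks_normality(c(1, 2)), "length >= 5")
})

test_that("Gaussian-centile thresholds are mean +/- k SD (sample SD)", {
  vals <- c(8, 10, 12) # mean 10, sd 2
  expect_equal(gaussian_threshold(vals, k = 1)$cutoff, 12)
  expect_equal(gaussian_threshold(vals, k = 2)$cutoff, 14)
  expect_equal(gaussian_threshold(vals, k = 1,
                                  direction = "low_is_sensitive")$cutoff, 8)
  expect_error(gaussian_threshold(vals, k = 3), "1 or 2")
  expect_error(gaussian_threshold(rep(5, 5), k = 1), "zero SD")
})

test_that("confusion metrics follow their definitions, undefined stays NA", {
  # perfect separation
  scores <- c(1, 2, 3, 10, 11, 12)
  grades <- c(0, 1, 1, 2, 3, 2)
  rule <- gaussian_threshold(scores, k = 1)
  # cutoff = 6.5 + 4.806 = 11.3: only partial -> craft a clean rule instead
  rule$cutoff <- 6
  cl <- classify_and_score(scores, grades, rule)
  expect_equal(c(cl$sensitivity, cl$specificity, cl$accuracy, cl$ppv, cl$npv),
               rep(100, 5))
  # all predicted negative: PPV undefined (0/0), never 0
  rule$cutoff <- 100
  cl <- classify_and_score(scores, grades, rule)
  expect_equal(cl$sensitivity, 0)
  expect_equal(cl$specificity, 100)
  expect_true(is.na(cl$ppv))
  expect_equal(cl$npv, 50)
  expect_error(classify_and_score(scores, rep(3, 6), rule), "single-class")
  # metric identity acc = (sens*P + spec*N)/(P+N) on random instances
  set.seed(6)
  for (i in 1:100) {
    n <- sample(10:40, 1)
    s <- stats::rnorm(n)
    g <- sample(0:4, n, replace = TRUE)
    if (all(g >= 2) || !any(g >= 2)) next
    r <- gaussian_threshold(s, k = 1)
    cl <- classify_and_score(s, g, r)
    p <- cl$tp + cl$fn; ng <- cl$tn + cl$fp
    expect_equal(cl$accuracy, (cl$sensitivity * p + cl$specificity * ng) /
                   (p + ng), tolerance = 1e-12)
  }
})

test_that("degenerate all-negative classifier at 36% prevalence", {
  grades <- rep(c(2, 1), c(18, 32))
  scores <- seq_along(grades) * 0.01
  rule <- gaussian_threshold(scores, k = 1)
  rule$cutoff <- 10 # beyond every score
  cl <- classify_and_score(scores, grades, rule)
  expect_equal(cl$sensitivity, 0)
  expect_equal(cl$specificity, 100)
  expect_equal(cl$accuracy, 64)
})

test_that("ROC handles perfect, uninformative and tied scores", {
  expect_equal(roc_analysis(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_analysis(rep(2, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)
  # frozen pair-counting value for scores (1,2,2,3,4), labels (0,0,1,1,1):
  # 5 concordant + 1 tie of 6 pos x neg pairs -> 11/12
  got <- roc_analysis(c(1, 2, 2, 3, 4), c(0, 0, 1, 1, 1))
  expect_equal(got$auc, 11 / 12, tolerance = 1e-12)
  expect_equal(got$auc, auc_pairs_oracle(c(1, 2, 2, 3, 4), c(0, 0, 1, 1, 1)))
  expect_error(roc_analysis(1:4, c(1, 1, 1, 1)), "single-class")
})

test_that("trapezoid AUC equals Mann-Whitney pair counting; symmetry holds", {
  set.seed(8)
  for (i in 1:300) {
    n <- sample(4:12, 1)
    s <- sample(1:6, n, replace = TRUE) # heavy ties on purpose
    l <- sample(c(0, 1), n, replace = TRUE)
    if (sum(l) == 0 || sum(l) == n) next
    a <- roc_analysis(s, l)$auc
    expect_rel_equal(a, auc_pairs_oracle(s, l), tol = 1e-12)
    # negating scores and flipping direction leaves AUC unchanged
    expect_equal(roc_analysis(-s, l, direction = "low")$auc, a,
                 tolerance = 1e-12)
  }
})

test_that("Youden cutoff maximises J with ties broken to specificity", {
  s <- c(1, 2, 3, 4, 5, 6)
  l <- c(0, 0, 1, 0, 1, 1)
  r <- roc_analysis(s, l)
  j <- r$points$sensitivity + r$points$specificity - 1
  expect_equal(r$optimal_sensitivity + r$optimal_specificity - 1, max(j))
  # J is maximised at cutoffs 3 and 5 (J = 2/3); tie goes to the higher
  # cutoff, i.e. higher specificity
  expect_equal(r$optimal_cutoff, 5)
  expect_equal(r$optimal_specificity, 1)
})

test_that("bootstrap AUC CI is stable under seed and covers the null", {
  set.seed(10)
  s <- stats::rnorm(60)
  l <- rep(c(0, 1), 30)
  ci1 <- roc_auc_ci(s, l, reps = 500, seed = 3)
  ci2 <- roc_auc_ci(s, l, reps = 500, seed = 3)
  expect_identical(ci1, ci2)
  expect_lte(ci1$conf_low, 0.5)
  expect_gte(ci1$conf_high, 0.5)
})

test_that("one-way ANOVA F matches the sums-of-squares oracle", {
  gm_tbl <- tibble::tibble(
    patient_id = rep(sprintf("P%d", 1:3), 2),
    dose_gy = rep(c(0, 2), each = 3), time_h = 0.5,
    gm = c(1, 2, 3, 3, 5, 7))
  got <- anova_across_doses(gm_tbl)
  expect_equal(got$f_statistic, 5.4, tolerance = 1e-12)
  expect_equal(got$f_statistic,
               anova_f_oracle(gm_tbl$gm, gm_tbl$dose_gy), tolerance = 1e-12)
  expect_equal(got$df_between, 1)
  expect_equal(got$df_within, 4)
  # identical values across groups -> F = 0
  flat <- dplyr::mutate(gm_tbl, gm = rep(c(1, 2, 3), 2))
  expect_equal(anova_across_doses(flat)$f_statistic, 0)
  expect_error(anova_across_doses(gm_tbl[gm_tbl$dose_gy == 0, ]), "2 dose")
})

test_that("Monte-Carlo Gaussian coverage matches the closed-form CDF", {
  cov <- gaussian_coverage(k = c(1, 2), n = 2e5, seed = 12)
  expect_equal(cov$coverage_exact_pct,
               100 * (stats::pnorm(c(1, 2)) - stats::pnorm(c(-1, -2))))
  expect_lt(max(abs(cov$coverage_mc_pct - cov$coverage_exact_pct)), 0.5)
})
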
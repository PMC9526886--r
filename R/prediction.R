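# Statistical layer: correlation with toxicity grade, normality assessment,
# Gaussian-centile thresholds, confusion-matrix metrics, and ROC analysis
# with the Youden-optimal cutoff.

#' Pearson correlation with p-value
#'
#' Product-moment correlation with a two-sided p-value from the t transform
#' on n - 2 degrees of freedom. Pairs with missing values are dropped
#' pairwise; zero variance in either variable is an error (not r = 0).
#'
#' @param x,y Numeric vectors of equal length.
#' @param index_name Optional label carried into the result.
#' @return One-row tibble: `index_name`, `r`, `p_value`, `n_used`.
#' @export
pearson_cor <- function(x, y, index_name = NA_character_) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) abort("need >= 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("zero variance: Pearson correlation undefined")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(index_name = index_name, r = unname(ct$estimate),
                 p_value = ct$p.value, n_used = length(x))
}

#' Kolmogorov-Smirnov assessment of Gaussian fit
#'
#' KS statistic of the sample against a Gaussian with the sample mean and SD,
#' with the standard asymptotic p-value, plus the R^2 of a Gaussian density
#' fitted to the sample histogram (the study summarises normality as an
#' adjusted R-square of the Gaussian function).
#'
#' The p-value uses the classical asymptotic distribution even though the
#' Gaussian parameters are estimated from the same sample; the Lilliefors
#' correction is deliberately not applied, matching common
#' statistics-software practice. The p is therefore conservative
#' (anti-conservative rejection is not a concern), which is adequate for a
#' descriptive normality check.
#'
#' @param x Numeric vector, n >= 5, nonzero variance.
#' @param breaks Histogram breaks specification (passed to [graphics::hist()]
#'   machinery via [hist][graphics::hist]'s algorithm; default Sturges).
#' @return One-row tibble: `n`, `statistic` (D), `p_value`, `fit_r2`,
#'   `fit_adj_r2`.
#' @export
ks_normality <- function(x, breaks = "Sturges") {
  assert_numeric_vec(x, "x", min_len = 5L)
  if (sd(x) == 0) abort("constant values: normality assessment undefined")
  ks <- suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  obs <- h$density
  pred <- dnorm(h$mids, mean(x), sd(x))
  ss_res <- sum((obs - pred)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  r2 <- 1 - ss_res / ss_tot
  m <- length(obs)
  adj <- 1 - (1 - r2) * (m - 1) / max(m - 3, 1)
  tibble::tibble(n = length(x), statistic = unname(ks$statistic),
                 p_value = ks$p.value, fit_r2 = r2, fit_adj_r2 = adj)
}

#' Gaussian-centile classification threshold
#'
#' The study's binary rule: under a Gaussian model of an index, 68% of
#' the population lies within one SD of the mean and 95% within two SD;
#' values beyond the band in the direction of sensitivity flag predicted
#' overreactors. Because only overreaction is the positive class, the
#' two-sided band collapses to a one-sided cutoff: `mean + k*SD` when high
#' values indicate sensitivity, `mean - k*SD` otherwise. SD uses the n - 1
#' denominator.
#'
#' @param values Index values across the cohort (n >= 3, nonzero SD).
#' @param k Centile multiplier, 1 (68th) or 2 (95th).
#' @param direction `"high_is_sensitive"` or `"low_is_sensitive"`.
#' @param index_name Optional label.
#' @return A `threshold_rule` object.
#' @examples
#' gaussian_threshold(c(8, 10, 12), k = 1) # cutoff = 10 + 2 = 12
#' @export
gaussian_threshold <- function(values, k = 1,
                               direction = c("high_is_sensitive",
                                             "low_is_sensitive"),
                               index_name = NA_character_) {
  direction <- match.arg(direction)
  values <- values[is.finite(values)]
  if (length(values) < 3L) abort("need >= 3 finite values")
  if (!k %in% c(1, 2)) abort("`k` must be 1 or 2")
  m <- mean(values); s <- sd(values)
  if (s == 0) abort("zero SD: threshold undefined")
  cutoff <- if (direction == "high_is_sensitive") m + k * s else m - k * s
  structure(list(index_name = index_name, direction = direction, k = k,
                 cutoff = cutoff, mean = m, sd = s, n = length(values)),
            class = "threshold_rule")
}

#' @export
print.threshold_rule <- function(x, ...) {
  cat(sprintf("<threshold_rule> %s: cutoff %.4g (mean %.4g %s %d SD = %.4g), n = %d\n",
              x$index_name, x$cutoff, x$mean,
              if (x$direction == "high_is_sensitive") "+" else "-",
              x$k, x$sd, x$n))
  invisible(x)
}

#' @method tidy threshold_rule
#' @export
tidy.threshold_rule <- function(x, ...) {
  tibble::tibble(index_name = x$index_name, direction = x$direction,
                 k = x$k, cutoff = x$cutoff, mean = x$mean, sd = x$sd,
                 n = x$n)
}

rule_predicts_positive <- function(scores, rule) {
  if (rule$direction == "high_is_sensitive") scores > rule$cutoff
  else scores < rule$cutoff
}

# Confusion counts -> metrics in percent; zero-denominator ratios are NA.
confusion_metrics <- function(tp, fp, tn, fn) {
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = pct(tp, tp + fn), specificity = pct(tn, tn + fp),
    accuracy = pct(tp + tn, tp + fp + tn + fn),
    ppv = pct(tp, tp + fp), npv = pct(tn, tn + fn)
  )
}

#' Score a threshold rule against observed toxicity grades
#'
#' Predicted-positive means the index lies beyond the rule's cutoff in the
#' sensitive direction; truly positive means the RTOG grade is at or above
#' `positive_grade` (the study's overreactor endpoint, grade >= 2). Ratios
#' with zero denominators (e.g. PPV with no predicted positives) are
#' reported as `NA`, never as 0.
#'
#' @param scores Per-patient index values.
#' @param grades Per-patient ordinal toxicity grades 0-4.
#' @param rule A [gaussian_threshold()] rule (or any `threshold_rule`).
#' @param positive_grade Minimum grade defining the positive class.
#' @return An `irs_classifier`: the rule, confusion counts and metrics (in
#'   percent).
#' @export
classify_and_score <- function(scores, grades, rule, positive_grade = 2) {
  stopifnot(inherits(rule, "threshold_rule"))
  if (length(scores) != length(grades)) {
    abort("`scores` and `grades` must have equal length")
  }
  ok <- is.finite(scores) & is.finite(grades)
  scores <- scores[ok]; grades <- grades[ok]
  if (any(grades < 0 | grades > 4)) abort("grades must be in 0..4")
  truth <- grades >= positive_grade
  if (all(truth) || !any(truth)) {
    abort("single-class truth vector: both classes required")
  }
  pred <- rule_predicts_positive(scores, rule)
  m <- confusion_metrics(tp = sum(pred & truth), fp = sum(pred & !truth),
                         tn = sum(!pred & !truth), fn = sum(!pred & truth))
  structure(c(list(rule = rule, n = length(scores),
                   positive_grade = positive_grade), as.list(m)),
            class = "irs_classifier")
}

#' @export
print.irs_classifier <- function(x, ...) {
  cat(sprintf("<irs_classifier> %s (cutoff %.4g, k = %d), n = %d\n",
              x$rule$index_name, x$rule$cutoff, x$rule$k, x$n))
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf(
    "  sens %.1f%%  spec %.1f%%  acc %.1f%%  PPV %s  NPV %s\n",
    x$sensitivity, x$specificity, x$accuracy,
    if (is.na(x$ppv)) "undefined" else sprintf("%.1f%%", x$ppv),
    if (is.na(x$npv)) "undefined" else sprintf("%.1f%%", x$npv)))
  invisible(x)
}

#' @method glance irs_classifier
#' @export
glance.irs_classifier <- function(x, ...) {
  tibble::tibble(index_name = x$rule$index_name, k = x$rule$k,
                 cutoff = x$rule$cutoff, n = x$n, tp = x$tp, fp = x$fp,
                 tn = x$tn, fn = x$fn, sensitivity = x$sensitivity,
                 specificity = x$specificity, accuracy = x$accuracy,
                 ppv = x$ppv, npv = x$npv)
}

#' @method tidy irs_classifier
#' @export
tidy.irs_classifier <- function(x, ...) {
  tidyr::pivot_longer(glance(x),
                      cols = c("sensitivity", "specificity", "accuracy",
                               "ppv", "npv"),
                      names_to = "metric", values_to = "percent")[
    , c("index_name", "k", "metric", "percent")]
}

#' ROC analysis with Youden-optimal cutoff
#'
#' Builds the ROC curve over thresholds at every distinct score value,
#' computes the AUC, and selects the cutoff maximising the Youden index
#' J = sensitivity + specificity - 1 (ties broken toward higher
#' specificity). The AUC is computed by the trapezoidal rule over the curve,
#' which — because tied scores contribute diagonal segments — equals the
#' Mann-Whitney pair-counting statistic (concordant pairs plus half the
#' tied pairs, over all positive x negative pairs) exactly.
#'
#' @param scores Numeric index values.
#' @param labels Logical (or 0/1) truth labels; `TRUE` = positive
#'   (overreactor).
#' @param direction `"high"` if larger scores indicate the positive class.
#' @return An `irs_roc`: list with `$points` (tibble `threshold`,
#'   `sensitivity`, `specificity`, `fpr`), `$auc`, `$optimal_cutoff`,
#'   `$optimal_sensitivity`, `$optimal_specificity`, `$optimal_method`
#'   (`"youden"`), `$n_pos`, `$n_neg`, `$direction`.
#' @export
roc_analysis <- function(scores, labels, direction = c("high", "low")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    abort("single-class labels: ROC undefined")
  }
  s <- if (direction == "high") scores else -scores
  # Sweep thresholds "predict positive iff s >= t" from above the maximum
  # (nothing positive) down through every distinct value.
  thr <- sort(unique(s), decreasing = TRUE)
  pos_at <- vapply(thr, function(t) sum(s >= t & labels), numeric(1))
  neg_at <- vapply(thr, function(t) sum(s >= t & !labels), numeric(1))
  sens <- c(0, pos_at / n_pos)
  fpr <- c(0, neg_at / n_neg)
  thresholds <- c(Inf, thr)
  auc <- sum(diff(fpr) * (head(sens, -1) + tail(sens, -1)) / 2)
  # Youden over the swept cutoffs; ties -> higher specificity (lower fpr).
  j <- sens - fpr
  best <- which(j >= max(j) - 1e-12) # tolerate 1-ulp ties like 1 - 1/3
  best <- best[which.min(fpr[best])]
  opt_thr <- thresholds[best]
  points <- tibble::tibble(
    threshold = if (direction == "high") thresholds else -thresholds,
    sensitivity = sens, specificity = 1 - fpr, fpr = fpr
  )
  structure(list(points = points, auc = auc,
                 optimal_cutoff = if (direction == "high") opt_thr else
                   -opt_thr,
                 optimal_sensitivity = sens[best],
                 optimal_specificity = 1 - fpr[best],
                 optimal_method = "youden",
                 n_pos = n_pos, n_neg = n_neg, direction = direction),
            class = "irs_roc")
}

#' @export
print.irs_roc <- function(x, ...) {
  cat(sprintf(
    "<irs_roc> AUC %.4f (%d pos / %d neg); Youden cutoff %.4g (sens %.1f%%, spec %.1f%%)\n",
    x$auc, x$n_pos, x$n_neg, x$optimal_cutoff,
    100 * x$optimal_sensitivity, 100 * x$optimal_specificity))
  invisible(x)
}

#' @method tidy irs_roc
#' @export
tidy.irs_roc <- function(x, ...) x$points

#' @method glance irs_roc
#' @export
glance.irs_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, optimal_cutoff = x$optimal_cutoff,
                 optimal_sensitivity = x$optimal_sensitivity,
                 optimal_specificity = x$optimal_specificity,
                 optimal_method = x$optimal_method,
                 n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Bootstrap confidence interval for the ROC AUC
#'
#' Percentile interval from a stratified nonparametric bootstrap (cases and
#' controls resampled separately, so every replicate has both classes).
#' This is an engineering addition beyond the study's own analysis, useful
#' for judging whether an AUC is distinguishable from 0.5.
#'
#' @inheritParams roc_analysis
#' @param reps Bootstrap replicates.
#' @param seed Seed for the resampling.
#' @param conf Confidence level.
#' @return One-row tibble: `auc`, `conf_low`, `conf_high`, `reps`, `conf`.
#' @export
roc_auc_ci <- function(scores, labels, direction = "high", reps = 2000,
                       seed = 1L, conf = 0.95) {
  labels <- as.logical(labels)
  base <- roc_analysis(scores, labels, direction)
  ip <- which(labels); ineg <- which(!labels)
  aucs <- withr::with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      idx <- c(sample(ip, replace = TRUE), sample(ineg, replace = TRUE))
      roc_analysis(scores[idx], labels[idx], direction)$auc
    }, numeric(1))
  })
  a <- (1 - conf) / 2
  tibble::tibble(auc = base$auc,
                 conf_low = unname(quantile(aucs, a)),
                 conf_high = unname(quantile(aucs, 1 - a)),
                 reps = reps, conf = conf)
}

#' One-way ANOVA of 30-min geometric means across doses
#'
#' Classical one-way analysis of variance of the per-patient induction-time
#' geometric mean grouped by dose, the study's test that the mean gamma-H2AX
#' response differs between 0, 1 and 2 Gy.
#'
#' @inheritParams cohort_dose_response
#' @return One-row tibble: `f_statistic`, `df_between`, `df_within`,
#'   `p_value`.
#' @export
anova_across_doses <- function(gm_tbl, time = 0.5) {
  df <- dplyr::filter(gm_tbl, .data$time_h == time)
  counts <- table(df$dose_gy)
  if (length(counts) < 2L) abort("need >= 2 dose groups")
  if (any(counts < 2L)) abort("each dose group needs >= 2 observations")
  fit <- aov(gm ~ factor(dose_gy), data = df)
  s <- summary(fit)[[1]]
  tibble::tibble(f_statistic = s[["F value"]][1],
                 df_between = s[["Df"]][1], df_within = s[["Df"]][2],
                 p_value = s[["Pr(>F)"]][1])
}

#' Gaussian centile coverage by Monte Carlo
#'
#' Fraction of standard-normal draws within `k` SD of the mean, alongside
#' the closed-form value `pnorm(k) - pnorm(-k)` — the calibration behind the
#' 68%/95% centile thresholds.
#'
#' @param k Vector of SD multipliers.
#' @param n Number of Monte-Carlo draws.
#' @param seed Seed.
#' @return Tibble: `k`, `coverage_mc_pct`, `coverage_exact_pct`.
#' @export
gaussian_coverage <- function(k = c(1, 2), n = 1e6, seed = 1L) {
  z <- withr::with_seed(seed, rnorm(n))
  tibble::tibble(
    k = k,
    coverage_mc_pct = vapply(k, function(kk) 100 * mean(abs(z) <= kk),
                             numeric(1)),
    coverage_exact_pct = 100 * (pnorm(k) - pnorm(-k))
  )
}
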
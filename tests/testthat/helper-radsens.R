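# Shared fixtures and independent brute-force oracles. The oracles
# deliberately use a different computational route than the package
# (sum-of-logs instead of mean-of-logs, explicit covariance sums instead of
# lm/cor.test, exhaustive pair counting instead of trapezoids).

tiny_config <- function(...) {
  cohort_config(n_patients = 3, events_per_sample = 200, seed = 42, ...)
}

# Noise-free limit: every event equals its generative geometric mean and
# the patient draws collapse to the configured means.
noise_free_config <- function(...) {
  defaults <- list(n_patients = 3, events_per_sample = 50, seed = 42,
                   event_cv = 0, induction_slope_sd = 0, baseline_gm_sd = 0,
                   repair_halflife_sd = 0, grade_noise_sd = 0,
                   debris_fraction = 0)
  do.call(cohort_config, utils::modifyList(defaults, list(...)))
}

# --- oracles -----------------------------------------------------------

# geometric mean via product-free log accumulation, one value at a time
gm_oracle <- function(x) {
  acc <- 0
  for (v in x) acc <- acc + log(v)
  exp(acc / length(x))
}

# closed-form OLS slope Sxy/Sxx
ols_slope_oracle <- function(x, y) {
  xb <- sum(x) / length(x); yb <- sum(y) / length(y)
  sum((x - xb) * (y - yb)) / sum((x - xb)^2)
}

# covariance-formula Pearson r
pearson_oracle <- function(x, y) {
  n <- length(x)
  xb <- sum(x) / n; yb <- sum(y) / n
  sxy <- sum((x - xb) * (y - yb))
  sxy / sqrt(sum((x - xb)^2) * sum((y - yb)^2))
}

# textbook sums-of-squares one-way ANOVA F
anova_f_oracle <- function(values, groups) {
  groups <- as.character(groups)
  grand <- mean(values)
  lv <- split(values, groups)
  ssb <- sum(vapply(lv, function(v) length(v) * (mean(v) - grand)^2,
                    numeric(1)))
  ssw <- sum(vapply(lv, function(v) sum((v - mean(v))^2), numeric(1)))
  dfb <- length(lv) - 1
  dfw <- length(values) - length(lv)
  (ssb / dfb) / (ssw / dfw)
}

# exhaustive pair-counting AUC: concordant + half ties over pos x neg pairs
auc_pairs_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

expect_rel_equal <- function(actual, expected, tol = 1e-10) {
  expect_lt(abs(actual - expected) / max(abs(expected),
                                         .Machine$double.eps), tol)
}
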
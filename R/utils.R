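# Internal argument checks shared across modules.

assert_number <- function(x, name, finite = TRUE, positive = FALSE,
                          nonnegative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name))
  }
  if (finite && !is.finite(x)) {
    abort(sprintf("`%s` must be finite.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0.", name))
  }
  if (nonnegative && x < 0) {
    abort(sprintf("`%s` must be >= 0.", name))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  assert_number(x, name)
  if (x < min || x != as.integer(x)) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

assert_numeric_vec <- function(x, name, min_len = 1L, finite = TRUE) {
  if (!is.numeric(x) || length(x) < min_len) {
    abort(sprintf("`%s` must be a numeric vector of length >= %d.",
                  name, min_len))
  }
  if (finite && !all(is.finite(x))) {
    abort(sprintf("`%s` must contain only finite values.", name))
  }
  invisible(x)
}

# Format doses/timepoints for file names and column labels: no trailing
# zeros, no scientific notation ("0.5", "3", "24").
num_label <- function(x) {
  vapply(x, function(v) format(v, trim = TRUE, scientific = FALSE),
         character(1))
}
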
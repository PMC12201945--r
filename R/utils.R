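clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# lognormal multiplier with unit mean and coefficient of variation cv
ln_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

stop_field <- function(field, msg) {
  abort(sprintf("invalid `%s`: %s", field, msg), class = "phycoflow_validation_error")
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stop_field(field, sprintf("must be a single integer >= %d", min))
  as.integer(x)
}

check_fraction <- function(x, field, lo = 0, hi = 1) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < lo) || any(x > hi))
    stop_field(field, sprintf("must lie in [%g, %g]", lo, hi))
  x
}

check_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0)
    abort(sprintf("%s is missing column(s): %s", what, paste(missing, collapse = ", ")),
          class = "phycoflow_validation_error")
  invisible(df)
}

# all permutations of seq_len(n); guarded because n! explodes
all_permutations <- function(n) {
  if (n > 8) abort("exhaustive permutations only supported for n <= 8")
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out[[i]] <- cbind(i, matrix(rest[sub], nrow = nrow(sub)))
  }
  do.call(rbind, out)
}

# pooled- or unequal-variance two-sample t-test that tolerates zero variance
safe_t_pvalue <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2 || length(y) < 2) return(NA_real_)
  if (sd(x) == 0 && sd(y) == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  tryCatch(t.test(x, y, var.equal = var_equal)$p.value, error = function(e) NA_real_)
}

adjust_p <- function(p, correction, n_tests = length(p)) {
  correction <- match.arg(correction, c("bonferroni", "holm", "BH", "none"))
  if (correction == "bonferroni") pmin(1, p * n_tests) else p.adjust(p, method = correction)
}
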
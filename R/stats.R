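#' Two-sample t-test on log-transformed data
#'
#' Two-tailed Student's t-test (pooled variance by default; Welch by flag)
#' computed on natural-log-transformed values -- the base of the logarithm
#' does not affect t or p. Raw-scale means and SEMs are reported alongside,
#' together with the percent difference of the raw means.
#'
#' @param a,b numeric samples, strictly positive (the log transform admits
#'   no zeros; offending records are named, never silently offset).
#' @param var_equal pooled variance (`TRUE`, Student) or Welch (`FALSE`).
#' @return A list of class `group_comparison`: `n_a`, `n_b`, `mean_a`,
#'   `sem_a`, `mean_b`, `sem_b`, `t`, `df`, `p`, `percent_diff`.
#' @examples
#' log_t_test(c(1.1, 1.4, 1.2), c(2.0, 2.3, 1.9))
#' @export
log_t_test <- function(a, b, var_equal = TRUE) {
  bad_a <- which(!is.finite(a) | a <= 0)
  bad_b <- which(!is.finite(b) | b <= 0)
  if (length(bad_a) || length(bad_b))
    stopf("log transform requires positive values; offending records: %s",
          paste(c(sprintf("a[%d]", bad_a), sprintf("b[%d]", bad_b)),
                collapse = ", "))
  if (length(a) < 2 || length(b) < 2)
    stopf("need n >= 2 per group")
  tt <- t.test(log(a), log(b), var.equal = var_equal)
  structure(
    list(n_a = length(a), n_b = length(b),
         mean_a = mean(a), sem_a = sem(a),
         mean_b = mean(b), sem_b = sem(b),
         t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value,
         percent_diff = 100 * (mean(b) - mean(a)) / mean(a)),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(paste0("<group_comparison> %.4g +/- %.2g (n=%d) vs ",
                     "%.4g +/- %.2g (n=%d): t=%.3f, p=%.3g (%+.1f%%)\n"),
              x$mean_a, x$sem_a, x$n_a, x$mean_b, x$sem_b, x$n_b,
              x$t, x$p, x$percent_diff))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' Correlation coefficient with a two-tailed p-value from the t transform
#' of r.
#'
#' @param x,y numeric vectors of equal length, n >= 3, non-degenerate.
#' @return A list: `r`, `p`, `n`.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y differ in length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stopf("need n >= 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stopf("correlation undefined: zero variance")
  ct <- cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Percent increase of one mean over another
#'
#' `100 * (mean_b - mean_a) / mean_a`: e.g. means of 233 and 203 a.u. give
#' a 14.8% (about 15%) increase.
#'
#' @param mean_b,mean_a the comparison and reference means; `mean_a > 0`.
#' @return Percent difference.
#' @export
percent_increase <- function(mean_b, mean_a) {
  if (!is_scalar_num(mean_a) || mean_a <= 0)
    stopf("reference mean must be > 0")
  100 * (mean_b - mean_a) / mean_a
}
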
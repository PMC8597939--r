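# Replicate aggregation and the two-group significance comparison.

#' Summarize replicate measurements
#'
#' Mean, sample standard deviation (n - 1 denominator) and relative
#' standard deviation RSD% = 100 * sd / mean, the dispersion currency
#' of dissolution and PAMPA reporting.
#'
#' @param values numeric vector, length >= 1.
#' @return List with `mean`, `sd`, `rsd_pct`, `n` and `rsd_defined`.
#'   With a single value `sd` and `rsd_pct` are `NA`; with zero mean
#'   RSD% is undefined and flagged (`rsd_defined = FALSE`).
#' @examples
#' summarize_group(c(1, 3))  # mean 2, sd sqrt(2), rsd 70.7%
#' @export
summarize_group <- function(values) {
  if (length(values) < 1) stop("need at least one value")
  if (any(!is.finite(values))) stop("values must be finite")
  n <- length(values)
  m <- mean(values)
  s <- if (n >= 2) stats::sd(values) else NA_real_
  rsd_defined <- is.finite(s) && m != 0
  list(mean = m, sd = s,
       rsd_pct = if (rsd_defined) 100 * s / m else NA_real_,
       n = n, rsd_defined = rsd_defined)
}

#' Compare two groups of measurements
#'
#' Welch's two-sample, two-sided t-test (unequal variances). Chosen
#' over the pooled-variance test because replicate dispersion in these
#' assays can differ grossly between groups (RSD% spanning tens of
#' percent).
#'
#' @param a,b numeric vectors, each with n >= 2.
#' @param alpha significance level; default 0.05.
#' @return List with `p_value`, `verdict` (`"significant"` iff
#'   p < alpha, else `"not_significant"`), `mean_a`, `mean_b`, `alpha`.
#' @examples
#' compare_groups(c(10, 10.1, 9.9, 10), c(20, 20.1, 19.9, 20))
#' @export
compare_groups <- function(a, b, alpha = 0.05) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  tt <- stats::t.test(a, b, alternative = "two.sided", var.equal = FALSE)
  p <- unname(tt$p.value)
  list(p_value = p,
       verdict = if (p < alpha) "significant" else "not_significant",
       mean_a = mean(a), mean_b = mean(b), alpha = alpha)
}
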
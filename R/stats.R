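# Group comparisons: unpaired two-tailed t-tests with the p < 0.05 /
# p < 0.001 star convention, box-plot summaries, percent changes.

#' Student's unpaired two-tailed t-test
#'
#' Pooled-variance (Student, not Welch) form with significance tier at the
#' 0.05 and 0.001 thresholds. Degenerate input with zero pooled variance
#' yields t = 0, p = 1 when the means are equal, and a flagged infinite-t,
#' p = 0 result when they differ.
#'
#' @param a,b numeric samples of size >= 2.
#' @return a `ttest_result`: `t_statistic`, `degrees_of_freedom`,
#'   `p_two_tailed`, `significance_tier` (`"ns"`, `"p<0.05"`, `"p<0.001"`),
#'   `mean_a`, `mean_b`, `degenerate` flag.
#' @export
ttest_unpaired <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stopf("both samples need >= 2 values")
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2)
  df <- length(a) + length(b) - 2
  degenerate <- sp2 == 0
  if (degenerate) {
    if (mean(a) == mean(b)) { t_stat <- 0; p <- 1 }
    else { t_stat <- sign(mean(a) - mean(b)) * Inf; p <- 0 }
  } else {
    ht <- stats::t.test(a, b, var.equal = TRUE)
    t_stat <- unname(ht$statistic)
    p <- ht$p.value
  }
  tier <- if (p < 0.001) "p<0.001" else if (p < 0.05) "p<0.05" else "ns"
  structure(list(t_statistic = t_stat, degrees_of_freedom = df,
                 p_two_tailed = p, significance_tier = tier,
                 mean_a = mean(a), mean_b = mean(b),
                 degenerate = degenerate),
            class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("<ttest_result> t = %.4f (df = %d), p = %.4g [%s]\n",
              x$t_statistic, x$degrees_of_freedom, x$p_two_tailed,
              x$significance_tier))
  invisible(x)
}

#' Box-plot summary of one group
#'
#' Quartiles use linear interpolation between order statistics
#' ([stats::quantile()] type 7); whiskers extend to the most extreme data
#' points within 1.5 IQR of the box.
#'
#' @param x numeric sample, n >= 1.
#' @return a `group_summary` list: `n`, `mean`, `sem`, `median`, `q25`,
#'   `q75`, `whisker_low`, `whisker_high`.
#' @export
group_summary <- function(x) {
  if (!length(x)) stopf("empty sample")
  q <- unname(stats::quantile(x, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  list(n = length(x), mean = mean(x),
       sem = if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0,
       median = q[2], q25 = q[1], q75 = q[3],
       whisker_low = min(x[x >= q[1] - 1.5 * iqr]),
       whisker_high = max(x[x <= q[3] + 1.5 * iqr]))
}

#' Signed percent change relative to a reference
#'
#' @param reference reference value (non-zero).
#' @param value new value.
#' @return `100 * (value - reference) / reference`.
#' @export
percent_change <- function(reference, value) {
  if (any(reference == 0)) stopf("reference must be non-zero")
  100 * (value - reference) / reference
}
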
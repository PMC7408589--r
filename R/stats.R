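## Shared statistics: standard error and the two-sample t-test used for
## per-timepoint / per-dose comparisons (alpha 0.05, no multiplicity
## correction — one comparison, one test).

#' Mean and standard error of a sample
#'
#' @param values numeric vector.
#' @return list of class `group_summary`: `mean`, `se` (`NA` and flagged
#'   `se_defined = FALSE` when n < 2), `n`.
#' @export
standard_error <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 1) stopf("need at least one value")
  n <- length(values)
  se <- if (n >= 2) stats::sd(values) / sqrt(n) else NA_real_
  structure(list(mean = mean(values), se = se, n = n, se_defined = n >= 2),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("mean %.6g, SE %s (n = %d)\n", x$mean,
              if (x$se_defined) sprintf("%.6g", x$se) else "undefined", x$n))
  invisible(x)
}

#' Two-sample two-sided t-test p-value
#'
#' Welch (unequal variance) by default; `var_equal = TRUE` gives the pooled
#' Student test.  When both groups have zero variance the test statistic is
#' undefined: equal means return p = 1 (no evidence of a difference, by
#' convention), unequal means return p = 0; both cases are messaged.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param var_equal pooled-variance Student test instead of Welch.
#' @return the p-value in `[0, 1]`.
#' @export
t_test <- function(a, b, var_equal = FALSE) {
  if (length(a) < 2 || length(b) < 2) stopf("each group needs n >= 2")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    p <- if (mean(a) == mean(b)) 1 else 0
    message(sprintf("t_test: both groups constant; p = %g by convention", p))
    return(p)
  }
  stats::t.test(a, b, var.equal = var_equal)$p.value
}
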
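# Normality-gated two-group comparison: Shapiro-Wilk on each group, then an
# unpaired two-sided Student's t-test if BOTH groups pass, otherwise a
# Mann-Whitney U test. The gate is conjunctive on purpose; all decisions are
# recorded so a reported p value can be traced to the test that produced it.

#' Significance star annotation
#'
#' Standard figure annotation with strict inequalities: `"ns"` for
#' p >= 0.05, then `"*"` (p < 0.05), `"**"` (p < 0.01), `"***"` (p < 0.001),
#' `"****"` (p < 0.0001); the most extreme applicable string is returned.
#'
#' @param p_value p value in `[0, 1]`.
#' @return annotation string.
#' @export
star_annotation <- function(p_value) {
  if (!is.numeric(p_value) || length(p_value) != 1L || is.na(p_value) ||
      p_value < 0 || p_value > 1)
    stop("p_value must be a single number in [0, 1]", call. = FALSE)
  if (p_value < 0.0001) "****"
  else if (p_value < 0.001) "***"
  else if (p_value < 0.01) "**"
  else if (p_value < 0.05) "*"
  else "ns"
}

shapiro_p <- function(x) {
  # identical values make W undefined; such a group is treated as failing
  # the normality gate (p = 0) rather than crashing
  if (stats::sd(x) == 0) return(0)
  stats::shapiro.test(x)$p.value
}

#' Normality-gated two-group comparison
#'
#' Tests each group with Shapiro-Wilk at `gate_alpha`; if both pass, the
#' difference in means is tested with an unpaired two-sided Student's t-test
#' (equal variances by default, `welch = TRUE` for the Welch form),
#' otherwise with a two-sided Mann-Whitney U test. Significance is assessed
#' at `alpha`. A zero-variance group cannot be tested parametrically and is
#' routed to Mann-Whitney with a warning.
#'
#' @param sample_a,sample_b numeric vectors, each of length >= 3.
#' @param alpha significance level of the comparison (default 0.05).
#' @param gate_alpha level of the normality gate (default 0.05).
#' @param welch use the Welch t-test instead of Student's when the
#'   parametric branch is taken.
#' @return a `comparison_result`: list with `n`, `shapiro_p`, `test_used`
#'   (`"t"` or `"mann_whitney"`), `statistic`, `p_value`, `significant`,
#'   `stars`, `alpha`, `gate_alpha`, `notes`.
#' @export
compare_groups <- function(sample_a, sample_b, alpha = 0.05,
                           gate_alpha = 0.05, welch = FALSE) {
  sample_a <- as.numeric(sample_a); sample_b <- as.numeric(sample_b)
  if (length(sample_a) < 3L || length(sample_b) < 3L)
    stop("each group needs at least 3 observations", call. = FALSE)
  notes <- character(0)
  zero_var <- stats::sd(sample_a) == 0 || stats::sd(sample_b) == 0
  if (zero_var) {
    warning("zero-variance group: falling back to Mann-Whitney U")
    notes <- c(notes, "zero-variance group; parametric branch unavailable")
  }
  p_a <- shapiro_p(sample_a); p_b <- shapiro_p(sample_b)
  normal <- !zero_var && p_a >= gate_alpha && p_b >= gate_alpha
  if (normal) {
    tt <- stats::t.test(sample_a, sample_b, var.equal = !welch)
    test_used <- "t"
    statistic <- unname(tt$statistic); p <- tt$p.value
  } else {
    wt <- suppressWarnings(stats::wilcox.test(sample_a, sample_b, exact = FALSE,
                                              correct = TRUE))
    test_used <- "mann_whitney"
    statistic <- unname(wt$statistic); p <- wt$p.value
  }
  structure(list(n = c(a = length(sample_a), b = length(sample_b)),
                 shapiro_p = c(a = p_a, b = p_b),
                 test_used = test_used, statistic = statistic,
                 p_value = p, significant = p < alpha,
                 stars = star_annotation(p),
                 alpha = alpha, gate_alpha = gate_alpha, notes = notes),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.4g, p = %.4g (%s), n = %d vs %d\n",
              if (x$test_used == "t") "Student's t" else "Mann-Whitney U",
              x$statistic, x$p_value, x$stars, x$n["a"], x$n["b"]))
  cat(sprintf("  Shapiro-Wilk gate (alpha = %g): p_a = %.3g, p_b = %.3g -> %s\n",
              x$gate_alpha, x$shapiro_p["a"], x$shapiro_p["b"],
              if (x$test_used == "t") "parametric" else "nonparametric"))
  for (nt in x$notes) cat("  note:", nt, "\n")
  invisible(x)
}

#' Optional multiple-testing adjustment
#'
#' Convenience wrapper over [stats::p.adjust()] for a set of comparisons;
#' no correction is applied by default anywhere in the package (per-condition
#' tests are reported unadjusted), this is opt-in.
#'
#' @param p_values numeric vector of p values.
#' @param method `"bonferroni"`, `"holm"`, or any [stats::p.adjust()] method.
#' @export
adjust_p_values <- function(p_values, method = c("holm", "bonferroni")) {
  method <- match.arg(method)
  stats::p.adjust(p_values, method = method)
}
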
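#' Two-sample comparison with automatic test selection
#'
#' Implements the group-comparison procedure used throughout the analyses:
#' normality of each group is assessed with Shapiro-Wilk at `alpha`; when
#' both groups are compatible with normality, variance homogeneity is
#' assessed with an F test at the same `alpha` to choose between Student's
#' and Welch's t test; otherwise the Mann-Whitney U test is used. All tests
#' are two-tailed. Group summaries are mean +/- SD on the parametric branch
#' and median +/- MAD (unscaled median absolute deviation) otherwise.
#' Constant samples (where Shapiro-Wilk is undefined) are routed to
#' Mann-Whitney with a warning.
#'
#' @param sample1,sample2 Numeric vectors, n >= 3 each.
#' @param alpha Significance level for the normality / variance screens.
#' @return An object of class `group_comparison`: `test_name` (one of
#'   `"student_t"`, `"welch_t"`, `"mann_whitney_u"`), `statistic`, `p_value`,
#'   `n1`, `n2`, `summary1`, `summary2` (each `location`, `spread`, `label`),
#'   and `fold_change` (location2 / location1).
#' @export
compare_groups <- function(sample1, sample2, alpha = 0.05) {
  for (s in list(sample1, sample2))
    if (!is.numeric(s) || sum(is.finite(s)) < 3L)
      stop("each sample must contain at least 3 finite values", call. = FALSE)
  x <- sample1[is.finite(sample1)]
  y <- sample2[is.finite(sample2)]

  constant <- stats::sd(x) == 0 || stats::sd(y) == 0
  if (constant) {
    warning("constant sample: normality screening bypassed, using Mann-Whitney U")
    normal <- FALSE
  } else {
    normal <- stats::shapiro.test(x)$p.value > alpha &&
      stats::shapiro.test(y)$p.value > alpha
  }

  if (normal) {
    equal_var <- stats::var.test(x, y)$p.value > alpha
    ht <- stats::t.test(x, y, var.equal = equal_var)
    test_name <- if (equal_var) "student_t" else "welch_t"
    s1 <- summary_loc(x, parametric = TRUE)
    s2 <- summary_loc(y, parametric = TRUE)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = !constant))
    test_name <- "mann_whitney_u"
    s1 <- summary_loc(x, parametric = FALSE)
    s2 <- summary_loc(y, parametric = FALSE)
  }

  structure(list(
    test_name = test_name,
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    n1 = length(x), n2 = length(y),
    summary1 = s1, summary2 = s2,
    fold_change = if (s1$location != 0) s2$location / s1$location else NA_real_
  ), class = "group_comparison")
}

summary_loc <- function(x, parametric) {
  if (parametric)
    list(location = mean(x), spread = stats::sd(x), label = "mean+/-SD")
  else
    list(location = stats::median(x),
         spread = stats::mad(x, constant = 1), label = "median+/-MAD")
}

#' @export
print.group_comparison <- function(x, ...) {
  fmt <- function(s, n) sprintf("%.4g +/- %.4g (%s, n=%d)",
                                s$location, s$spread, s$label, n)
  cat(sprintf("Two-sample comparison (%s, two-tailed)\n", x$test_name))
  cat("  group 1:", fmt(x$summary1, x$n1), "\n")
  cat("  group 2:", fmt(x$summary2, x$n2), "\n")
  cat(sprintf("  statistic %.4g, p = %.4g, fold change %.4g\n",
              x$statistic, x$p_value, x$fold_change))
  invisible(x)
}

#' Location/spread summary with normality-dependent form
#'
#' Mean +/- SD when the sample is compatible with normality (Shapiro-Wilk at
#' `alpha`), median +/- unscaled MAD otherwise. Samples too small for the
#' normality test (n < 3) or constant samples default to mean +/- SD.
#'
#' @param sample Numeric vector, n >= 1.
#' @param alpha Significance level of the normality screen.
#' @return A list: `location`, `spread`, `label`.
#' @export
summarize_sample <- function(sample, alpha = 0.05) {
  x <- sample[is.finite(sample)]
  if (!length(x)) stop("empty sample", call. = FALSE)
  if (length(x) < 3L || stats::sd(x) == 0)
    return(summary_loc(x, parametric = TRUE))
  summary_loc(x, parametric = stats::shapiro.test(x)$p.value > alpha)
}
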
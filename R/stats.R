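#' Container for a single test result
#' @param test test name.
#' @param estimate point estimate (or `NA`).
#' @param conf_low,conf_high 95% confidence limits (or `NA`).
#' @param p_value two-sided p-value.
#' @param n sample size (or per-group vector).
#' @param auxiliary named list of auxiliary statistics (W, U, rho, t, df, ...).
#' @export
stat_result <- function(test, estimate = NA_real_, conf_low = NA_real_,
                        conf_high = NA_real_, p_value = NA_real_, n = NA,
                        auxiliary = list()) {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1))
    tf_stop("p-value outside [0, 1]", "tf_domain_error")
  if (!is.na(conf_low) && !is.na(conf_high) && !is.na(estimate) &&
      (conf_low > estimate || estimate > conf_high))
    tf_stop("estimate outside its confidence interval", "tf_domain_error")
  structure(list(test = test, estimate = estimate, conf_low = conf_low,
                 conf_high = conf_high, p_value = p_value, n = n,
                 auxiliary = auxiliary), class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<%s> estimate %.4g", x$test, x$estimate))
  if (!is.na(x$conf_low)) cat(sprintf(" [%.4g, %.4g]", x$conf_low, x$conf_high))
  cat(sprintf(", p = %.4g, n = %s\n", x$p_value, paste(x$n, collapse = "/")))
  if (length(x$auxiliary))
    cat(" ", paste(sprintf("%s = %.4g", names(x$auxiliary),
                           unlist(x$auxiliary)), collapse = ", "), "\n")
  invisible(x)
}

#' Descriptive summary of a sample
#'
#' Mean with SD (n - 1 denominator) and median with interquartile range
#' (25th/75th percentiles, linear interpolation), plus range.
#' @param values numeric sample, n >= 1.
#' @return one-row tibble.
#' @export
describe <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0 || all(is.na(values)))
    tf_stop("empty sample", "tf_empty_input")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble::tibble(
    n = length(values),
    mean = mean(values),
    sd = if (length(values) > 1) stats::sd(values) else 0,
    median = q[2], q25 = q[1], q75 = q[3], iqr = q[3] - q[1],
    min = min(values), max = max(values))
}

#' Shapiro-Wilk normality test
#'
#' Gate for parametric vs non-parametric downstream tests (at alpha = 0.05).
#' @param values numeric sample, 3 <= n <= 5000.
#' @export
shapiro_wilk <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3 || n > 5000)
    tf_stop("Shapiro-Wilk requires 3 <= n <= 5000", "tf_sample_size_error")
  r <- stats::shapiro.test(values)
  stat_result("shapiro_wilk", estimate = unname(r$statistic),
              p_value = r$p.value, n = n,
              auxiliary = list(W = unname(r$statistic)))
}

#' Spearman rank correlation
#'
#' rho via Pearson correlation of average ranks; two-sided p from the
#' t approximation (robust to ties).
#' @param x,y paired numeric samples, n >= 3.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y))
    tf_stop("x and y must be paired (equal length)", "tf_pairing_error")
  n <- length(x)
  if (n < 3) tf_stop("Spearman correlation requires n >= 3", "tf_sample_size_error")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  stat_result("spearman", estimate = rho, p_value = p, n = n,
              auxiliary = list(rho = rho))
}

#' Paired t-test with confidence interval
#'
#' Mean within-subject difference `a - b` with its 95% CI from the t
#' quantile on n - 1 degrees of freedom. Also callable from summary
#' statistics of the differences (`mean_diff`, `sd_diff`, `n`), the form
#' used to recompute printed results.
#'
#' @param a,b paired samples (or `NULL` when using summary input).
#' @param mean_diff,sd_diff,n summary statistics of the differences.
#' @param conf_level confidence level.
#' @export
paired_t_with_ci <- function(a = NULL, b = NULL, mean_diff = NULL,
                             sd_diff = NULL, n = NULL, conf_level = 0.95) {
  if (!is.null(a) || !is.null(b)) {
    if (length(a) != length(b))
      tf_stop("a and b must be paired (equal length)", "tf_pairing_error")
    if (length(a) < 2)
      tf_stop("paired t-test requires n >= 2", "tf_sample_size_error")
    d <- as.numeric(a) - as.numeric(b)
    mean_diff <- mean(d)
    sd_diff <- stats::sd(d)
    n <- length(d)
  }
  if (is.null(mean_diff) || is.null(sd_diff) || is.null(n))
    tf_stop("provide either paired samples or (mean_diff, sd_diff, n)",
            "tf_domain_error")
  if (n < 2) tf_stop("paired t-test requires n >= 2", "tf_sample_size_error")
  if (sd_diff <= 0)
    tf_stop("zero variance of paired differences", "tf_degenerate_variance")
  se <- sd_diff / sqrt(n)
  tstat <- mean_diff / se
  df <- n - 1
  tq <- stats::qt(1 - (1 - conf_level) / 2, df)
  stat_result("paired_t", estimate = mean_diff,
              conf_low = mean_diff - tq * se, conf_high = mean_diff + tq * se,
              p_value = 2 * stats::pt(-abs(tstat), df), n = n,
              auxiliary = list(t = tstat, df = df, sd_diff = sd_diff))
}

#' Express a difference (with CI) as a percentage of a reference mean
#'
#' Each of estimate, CI low and CI high is divided by the reference mean and
#' multiplied by 100, then rounded to 2 decimals for reporting.
#' @param diff a `stat_result` (or list with `estimate`, `conf_low`,
#'   `conf_high`).
#' @param reference_mean positive reference (mm^3).
#' @export
percent_of_mean_with_ci <- function(diff, reference_mean) {
  if (!is.numeric(reference_mean) || reference_mean <= 0)
    tf_stop("reference mean must be positive", "tf_domain_error")
  out <- c(estimate = diff$estimate, low = diff$conf_low,
           high = diff$conf_high) / reference_mean * 100
  round(out, 2)
}

#' Levene's test for equality of variances (classical, centre = mean)
#'
#' One-way ANOVA F statistic on the absolute deviations from the group
#' means.
#' @param g1,g2 numeric samples, each n >= 2.
#' @export
levene <- function(g1, g2) {
  if (length(g1) < 2 || length(g2) < 2)
    tf_stop("Levene's test requires n >= 2 per group", "tf_sample_size_error")
  z1 <- abs(g1 - mean(g1))
  z2 <- abs(g2 - mean(g2))
  n1 <- length(z1); n2 <- length(z2); N <- n1 + n2; k <- 2
  zb <- mean(c(z1, z2))
  ssb <- n1 * (mean(z1) - zb)^2 + n2 * (mean(z2) - zb)^2
  ssw <- sum((z1 - mean(z1))^2) + sum((z2 - mean(z2))^2)
  if (ssw == 0) {
    fstat <- if (ssb == 0) 0 else Inf
    p <- if (ssb == 0) 1 else 0
  } else {
    fstat <- (ssb / (k - 1)) / (ssw / (N - k))
    p <- stats::pf(fstat, k - 1, N - k, lower.tail = FALSE)
  }
  stat_result("levene", estimate = fstat, p_value = p, n = c(n1, n2),
              auxiliary = list(F = fstat, df1 = k - 1, df2 = N - k))
}

#' Two-sample t-test, Levene-gated
#'
#' Student's pooled-variance form when Levene's test does not reject
#' equality of variances at `alpha` (and always for summary-statistic
#' input), Welch's form otherwise.
#'
#' @param g1,g2 numeric samples (each n >= 2), or `NULL` for summary input.
#' @param m1,s1,n1,m2,s2,n2 summary statistics (means, SDs, sizes).
#' @param alpha variance-gate significance level.
#' @param var_equal force the pooled form (summary input default).
#' @export
two_sample_t <- function(g1 = NULL, g2 = NULL, m1 = NULL, s1 = NULL, n1 = NULL,
                         m2 = NULL, s2 = NULL, n2 = NULL, alpha = 0.05,
                         var_equal = NULL) {
  if (!is.null(g1) || !is.null(g2)) {
    if (length(g1) < 2 || length(g2) < 2)
      tf_stop("two-sample t-test requires n >= 2 per group", "tf_sample_size_error")
    lev <- levene(g1, g2)
    if (is.null(var_equal)) var_equal <- lev$p_value > alpha
    r <- stats::t.test(g1, g2, var.equal = var_equal)
    return(stat_result("two_sample_t", estimate = mean(g1) - mean(g2),
                       conf_low = r$conf.int[1], conf_high = r$conf.int[2],
                       p_value = r$p.value, n = c(length(g1), length(g2)),
                       auxiliary = list(t = unname(r$statistic),
                                        df = unname(r$parameter),
                                        levene_p = lev$p_value,
                                        var_equal = var_equal)))
  }
  if (is.null(m1) || is.null(s1) || is.null(n1) ||
      is.null(m2) || is.null(s2) || is.null(n2))
    tf_stop("provide either two samples or full summary statistics",
            "tf_domain_error")
  if (n1 < 2 || n2 < 2)
    tf_stop("two-sample t-test requires n >= 2 per group", "tf_sample_size_error")
  if (is.null(var_equal)) var_equal <- TRUE
  if (var_equal) {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se <- sqrt(s1^2 / n1 + s2^2 / n2)
    df <- se^4 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  }
  if (se == 0) tf_stop("degenerate variances in both groups", "tf_degenerate_variance")
  tstat <- (m1 - m2) / se
  tq <- stats::qt(0.975, df)
  stat_result("two_sample_t", estimate = m1 - m2,
              conf_low = m1 - m2 - tq * se, conf_high = m1 - m2 + tq * se,
              p_value = 2 * stats::pt(-abs(tstat), df), n = c(n1, n2),
              auxiliary = list(t = tstat, df = df, var_equal = var_equal))
}

#' Mann-Whitney U test
#'
#' Exact two-sided p by enumeration when `n1 * n2 <= 400` and there are no
#' ties; otherwise the normal approximation with tie and continuity
#' correction. U is reported for the first group.
#' @param g1,g2 numeric samples, each n >= 1.
#' @export
mann_whitney <- function(g1, g2) {
  if (length(g1) < 1 || length(g2) < 1)
    tf_stop("Mann-Whitney requires non-empty groups", "tf_sample_size_error")
  ties <- anyDuplicated(c(g1, g2)) > 0
  use_exact <- (length(g1) * length(g2) <= 400) && !ties
  r <- suppressWarnings(stats::wilcox.test(g1, g2, exact = use_exact,
                                           correct = TRUE))
  u <- unname(r$statistic)
  stat_result("mann_whitney", estimate = u, p_value = r$p.value,
              n = c(length(g1), length(g2)),
              auxiliary = list(U = u, exact = use_exact))
}

#' Cohen's dz (paired effect size)
#' @param mean_diff mean of within-subject differences.
#' @param sd_diff SD of the differences, > 0.
#' @export
cohen_dz <- function(mean_diff, sd_diff) {
  if (!is.numeric(sd_diff) || sd_diff <= 0)
    tf_stop("sd_diff must be positive", "tf_domain_error")
  mean_diff / sd_diff
}

#' Cohen's d (two-sample, pooled SD)
#' @param m1,s1,n1,m2,s2,n2 group means, SDs and sizes.
#' @export
cohen_d_pooled <- function(m1, s1, n1, m2, s2, n2) {
  if (s1 <= 0 || s2 <= 0 || n1 < 2 || n2 < 2)
    tf_stop("need positive SDs and n >= 2 per group", "tf_domain_error")
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  abs(m1 - m2) / sp
}
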
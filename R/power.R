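# Achieved (post hoc) power for the three test families used in the
# cohort analysis: noncentral-t power for the paired and two-sample t-tests,
# and the Fisher-z normal approximation for a correlation.

#' Achieved power of a two-sided paired t-test
#'
#' Noncentral-t power with noncentrality `dz * sqrt(n)` and `n - 1` degrees
#' of freedom. Equals `alpha` at `dz = 0`.
#' @param dz Cohen's dz (paired effect size).
#' @param n number of pairs, >= 2.
#' @param alpha two-sided significance level.
#' @export
power_paired_t <- function(dz, n, alpha = 0.05) {
  if (!is.numeric(n) || n < 2 || alpha <= 0 || alpha >= 1)
    tf_stop("need n >= 2 and alpha in (0, 1)", "tf_domain_error")
  df <- n - 1
  ncp <- abs(dz) * sqrt(n)
  tcrit <- stats::qt(1 - alpha / 2, df)
  stats::pt(-tcrit, df, ncp) + stats::pt(tcrit, df, ncp, lower.tail = FALSE)
}

#' Achieved power of a two-sided two-sample t-test
#'
#' Noncentral-t power with noncentrality `d * sqrt(n1 n2 / (n1 + n2))` and
#' `n1 + n2 - 2` degrees of freedom.
#' @param d Cohen's d (pooled).
#' @param n1,n2 group sizes, each >= 2.
#' @param alpha two-sided significance level.
#' @export
power_two_sample_t <- function(d, n1, n2, alpha = 0.05) {
  if (n1 < 2 || n2 < 2 || alpha <= 0 || alpha >= 1)
    tf_stop("need n1, n2 >= 2 and alpha in (0, 1)", "tf_domain_error")
  df <- n1 + n2 - 2
  ncp <- abs(d) * sqrt(n1 * n2 / (n1 + n2))
  tcrit <- stats::qt(1 - alpha / 2, df)
  stats::pt(-tcrit, df, ncp) + stats::pt(tcrit, df, ncp, lower.tail = FALSE)
}

#' Achieved power to detect a correlation (Fisher z approximation)
#'
#' `power = Phi(|atanh(rho)| sqrt(n - 3) - z_{1-alpha/2}) +
#'          Phi(-|atanh(rho)| sqrt(n - 3) - z_{1-alpha/2})`.
#' @param rho population correlation, |rho| < 1.
#' @param n sample size, >= 4.
#' @param alpha two-sided significance level.
#' @export
power_correlation_fisher_z <- function(rho, n, alpha = 0.05) {
  if (abs(rho) >= 1) tf_stop("|rho| must be < 1", "tf_domain_error")
  if (n < 4) tf_stop("correlation power requires n >= 4", "tf_domain_error")
  if (alpha <= 0 || alpha >= 1) tf_stop("alpha must be in (0, 1)", "tf_domain_error")
  zr <- abs(atanh(rho)) * sqrt(n - 3)
  zc <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(zr - zc) + stats::pnorm(-zr - zc)
}
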
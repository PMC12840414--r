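#' Validate a cohort table
#'
#' Checks the per-subject schema (`subject_id`, `sex`, `age`, `v_total`,
#' `v_superimposed`, optionally `rtv` and `pct_si`, which are derived when
#' absent) and the record invariants: volumes positive,
#' `rtv = v_total - v_superimposed` within 1e-6 relative, `pct_si` in
#' [0, 100], `age > 0`. Violations are reported with their row numbers.
#'
#' @param cohort data frame.
#' @return validated tibble with all derived columns.
#' @export
validate_cohort <- function(cohort) {
  required <- c("subject_id", "sex", "age", "v_total", "v_superimposed")
  missing <- setdiff(required, names(cohort))
  if (length(missing))
    tf_stop(paste("missing cohort column(s):", paste(missing, collapse = ", ")),
            "tf_schema_error")
  cohort <- tibble::as_tibble(cohort)
  cohort$sex <- tolower(as.character(cohort$sex))
  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows))
      tf_stop(sprintf("%s at row(s) %s", what,
                      paste(utils::head(rows, 10), collapse = ", ")),
              "tf_schema_error")
  }
  bad(!cohort$sex %in% c("female", "male"), "sex must be female/male")
  bad(!is.finite(cohort$age) | cohort$age <= 0, "age must be positive")
  bad(!is.finite(cohort$v_total) | cohort$v_total <= 0,
      "v_total must be positive")
  bad(!is.finite(cohort$v_superimposed) | cohort$v_superimposed < 0,
      "v_superimposed must be non-negative")
  bad(cohort$v_superimposed > cohort$v_total * (1 + 1e-9),
      "v_superimposed exceeds v_total")
  if (!"rtv" %in% names(cohort)) {
    cohort$rtv <- cohort$v_total - cohort$v_superimposed
  } else {
    bad(abs(cohort$rtv - (cohort$v_total - cohort$v_superimposed)) >
          1e-6 * cohort$v_total, "rtv inconsistent with v_total - v_superimposed")
  }
  if (!"pct_si" %in% names(cohort)) {
    cohort$pct_si <- cohort$v_superimposed / cohort$v_total * 100
  } else {
    bad(cohort$pct_si < 0 | cohort$pct_si > 100, "pct_si outside [0, 100]")
  }
  cohort
}

#' Read a cohort CSV
#' @param path CSV with header columns `subject_id, sex, age, v_total,
#'   v_superimposed[, rtv, pct_si]`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) tf_stop(paste("file not found:", path), "tf_schema_error")
  validate_cohort(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a cohort CSV
#' @param cohort cohort tibble.
#' @param path output path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

try_stat <- function(expr) {
  tryCatch(expr, toothface_error = function(e)
    list(error = conditionMessage(e), class = class(e)[1]))
}

is_stat_error <- function(x) !inherits(x, "stat_result") && !is.null(x$error)

#' Full cohort analysis report
#'
#' Runs the complete statistical battery on a cohort table: overall
#' descriptives; Shapiro-Wilk normality gating; Spearman correlation of
#' total vs remaining volume overall and per subgroup (sex, age < 21 vs
#' >= 21); the paired total-vs-superimposed comparison with 95% CI,
#' percent-of-mean, Cohen's dz and achieved power, overall and per
#' subgroup; sex and age-group comparisons of total volume and %SI via
#' the Levene-gated Student t (normal variables) or Mann-Whitney U
#' (non-normal), with Cohen's d and achieved power. Tests that cannot run
#' (e.g. a one-row cohort) are returned as collected error records, not
#' raised. Deterministic for a fixed input table.
#'
#' @param cohort cohort data frame (validated by [validate_cohort()]).
#' @param alpha significance level for every test and gate.
#' @param age_cut age-group boundary (years); groups are `< age_cut` and
#'   `>= age_cut`.
#' @return a nested list of `stat_result`s, tibbles and error records.
#' @export
analysis_report <- function(cohort, alpha = 0.05, age_cut = 21) {
  cohort <- validate_cohort(cohort)
  n <- nrow(cohort)
  groups <- list(
    overall = rep(TRUE, n),
    female = cohort$sex == "female",
    male = cohort$sex == "male",
    under_21 = cohort$age < age_cut,
    at_least_21 = cohort$age >= age_cut)

  vars <- c("age", "v_total", "v_superimposed", "rtv", "pct_si")
  descr <- do.call(rbind, lapply(vars, function(v)
    cbind(tibble::tibble(variable = v), describe(cohort[[v]]))))

  normality <- lapply(stats::setNames(vars, vars), function(v)
    try_stat(shapiro_wilk(cohort[[v]])))
  gate_normal <- function(x) inherits(x, "stat_result") && x$p_value > alpha

  correlations <- lapply(groups, function(idx) {
    try_stat(spearman(cohort$v_total[idx], cohort$rtv[idx]))
  })

  paired <- lapply(groups, function(idx) {
    res <- try_stat(paired_t_with_ci(cohort$v_total[idx],
                                     cohort$v_superimposed[idx]))
    if (is_stat_error(res)) return(res)
    m <- mean(cohort$v_total[idx])
    dz <- res$estimate / res$auxiliary$sd_diff
    list(test = res,
         percent_of_mean = percent_of_mean_with_ci(res, m),
         cohen_dz = dz,
         achieved_power = power_paired_t(dz, sum(idx), alpha))
  })

  compare_groups <- function(idx1, idx2, var) {
    g1 <- cohort[[var]][idx1]
    g2 <- cohort[[var]][idx2]
    if (length(g1) < 3 || length(g2) < 3)
      return(try_stat(tf_stop("subgroup too small for comparison",
                              "tf_sample_size_error")))
    normal <- gate_normal(try_stat(shapiro_wilk(g1))) &&
      gate_normal(try_stat(shapiro_wilk(g2)))
    if (normal) {
      res <- try_stat(two_sample_t(g1, g2, alpha = alpha))
      if (is_stat_error(res)) return(res)
      d <- cohen_d_pooled(mean(g1), stats::sd(g1), length(g1),
                          mean(g2), stats::sd(g2), length(g2))
      list(test = res, route = "student_t", cohen_d = d,
           achieved_power = power_two_sample_t(d, length(g1), length(g2), alpha))
    } else {
      res <- try_stat(mann_whitney(g1, g2))
      if (is_stat_error(res)) return(res)
      list(test = res, route = "mann_whitney")
    }
  }

  comparisons <- list(
    sex = list(
      v_total = compare_groups(groups$female, groups$male, "v_total"),
      pct_si = compare_groups(groups$female, groups$male, "pct_si")),
    age_group = list(
      v_total = compare_groups(groups$under_21, groups$at_least_21, "v_total"),
      pct_si = compare_groups(groups$under_21, groups$at_least_21, "pct_si")))

  age_correlations <- list(
    age_vs_v_total = try_stat(spearman(cohort$age, cohort$v_total)),
    age_vs_pct_si = try_stat(spearman(cohort$age, cohort$pct_si)))

  list(
    sample = list(
      n = n,
      sex = c(female = sum(groups$female), male = sum(groups$male)),
      age_groups = c(under = sum(groups$under_21),
                     at_least = sum(groups$at_least_21)),
      alpha = alpha, age_cut = age_cut),
    descriptives = descr,
    normality = normality,
    correlations = correlations,
    age_correlations = age_correlations,
    paired = paired,
    comparisons = comparisons)
}
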
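test_that("descriptives use n-1 SD and interpolated quartiles", {
  d <- describe(c(1, 2, 3))
  expect_equal(d$mean, 2)
  expect_equal(d$sd, 1)
  dc <- describe(rep(7, 10))
  expect_equal(dc$sd, 0)
  expect_equal(dc$iqr, 0)
  d100 <- describe(1:100)
  expect_equal(d100$median, 50.5)
  expect_equal(d100$q25, 25.75)
  expect_equal(d100$q75, 75.25)
  expect_tf_error(describe(numeric(0)), "tf_empty_input")
})

test_that("Shapiro-Wilk gate behaves correctly under null and skewed alternatives", {
  expect_tf_error(shapiro_wilk(c(1, 2)), "tf_sample_size_error")
  # level under the null: p > 0.05 in at least 90% of seeded normal samples
  ok <- sum(vapply(1:100, function(s) {
    x <- withr::with_seed(s, rnorm(500))
    shapiro_wilk(x)$p_value > 0.05
  }, logical(1)))
  expect_gte(ok, 90)
  # power against a strongly right-skewed alternative
  for (s in 1:5) {
    x <- withr::with_seed(s, rnorm(500)^2)
    expect_lt(shapiro_wilk(x)$p_value, 0.001)
  }
})

test_that("Spearman correlation matches the rank formula and handles monotone cases", {
  # 1 - 6 sum(d^2) / (n (n^2-1)) with d = (1,1,1,1): rho = 0.6
  r <- spearman(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(r$estimate, 0.6, tolerance = 1e-12)
  x <- c(0.3, 1.1, 2.7, 5, 9.2)
  expect_equal(spearman(x, exp(x))$estimate, 1)
  expect_equal(spearman(x, rev(x) * -1)$estimate, 1)
  expect_equal(spearman(x, -x^3)$estimate, -1)
  expect_tf_error(spearman(1:4, 1:5), "tf_pairing_error")
  expect_tf_error(spearman(1:2, 2:1), "tf_sample_size_error")
  # agreement with the reference implementation (ties included)
  xt <- c(1, 2, 2, 3, 5, 5, 7)
  yt <- c(2, 1, 4, 4, 6, 8, 9)
  ref <- suppressWarnings(cor.test(xt, yt, method = "spearman"))
  expect_equal(spearman(xt, yt)$estimate, unname(ref$estimate),
               tolerance = 1e-12)
})

test_that("paired t with CI matches hand computation and the printed summary case", {
  # differences {1,2,3}: mean 2, sd 1, CI = 2 +/- 4.302653 / sqrt(3)
  r <- paired_t_with_ci(c(2, 4, 6), c(1, 2, 3))
  expect_equal(r$estimate, 2)
  expect_equal(r$conf_low, 2 - qt(0.975, 2) / sqrt(3), tolerance = 1e-9)
  expect_equal(r$conf_high, 2 + qt(0.975, 2) / sqrt(3), tolerance = 1e-9)
  ref <- t.test(c(2, 4, 6), c(1, 2, 3), paired = TRUE)
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(c(r$conf_low, r$conf_high), as.numeric(ref$conf.int),
               tolerance = 1e-12)
  # summary input reproduces the printed interval to the nearest integer
  rs <- paired_t_with_ci(mean_diff = 285052.34, sd_diff = 137012.73, n = 98)
  expect_equal(round(rs$conf_low), 257583)
  expect_equal(round(rs$conf_high), 312522)
  expect_lt(abs(rs$conf_high - 312521), 1)
  expect_tf_error(paired_t_with_ci(c(1, 2, 3), c(1, 2, 3)),
                  "tf_degenerate_variance")
  expect_tf_error(paired_t_with_ci(1:3, 1:4), "tf_pairing_error")
})

test_that("percent-of-mean reporting reproduces all four printed subgroup rows", {
  rs <- paired_t_with_ci(mean_diff = 285052.34, sd_diff = 137012.73, n = 98)
  expect_equal(unname(percent_of_mean_with_ci(rs, 1626120.79)),
               c(17.53, 15.84, 19.22))
  women <- list(estimate = 285296.23, conf_low = 248004, conf_high = 322587)
  expect_equal(unname(percent_of_mean_with_ci(women, 1583561)),
               c(18.02, 15.66, 20.37))
  men <- list(estimate = 284593.25, conf_low = 245379, conf_high = 323807)
  expect_equal(unname(percent_of_mean_with_ci(men, 1706232)),
               c(16.68, 14.38, 18.98))
  young <- list(estimate = 294131.51, conf_low = 253799, conf_high = 334463)
  expect_equal(unname(percent_of_mean_with_ci(young, 1652082)),
               c(17.80, 15.36, 20.24))
  zero <- list(estimate = 0, conf_low = 0, conf_high = 0)
  expect_equal(unname(percent_of_mean_with_ci(zero, 100)), c(0, 0, 0))
  expect_tf_error(percent_of_mean_with_ci(zero, 0), "tf_domain_error")
})

test_that("Levene's test equals one-way ANOVA on absolute mean deviations", {
  ident <- levene(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$estimate, 0)
  expect_equal(ident$p_value, 1)
  # hand case {1,2,3} vs {1,5,9}: F = 6 / (34/12) = 72/34
  r <- levene(c(1, 2, 3), c(1, 5, 9))
  expect_equal(r$estimate, 72 / 34, tolerance = 1e-12)
  # cross-check against the reference implementation (centre = mean)
  dat <- data.frame(y = c(1, 2, 3, 1, 5, 9),
                    g = factor(rep(c("a", "b"), each = 3)))
  ref <- car::leveneTest(y ~ g, data = dat, center = mean)
  expect_equal(r$estimate, ref[1, "F value"], tolerance = 1e-9)
  expect_equal(r$p_value, ref[1, "Pr(>F)"], tolerance = 1e-9)
  # level under equal variances
  ok <- sum(vapply(1:100, function(s) {
    g <- withr::with_seed(s, list(rnorm(200), rnorm(200, 5, 1)))
    levene(g[[1]], g[[2]])$p_value > 0.05
  }, logical(1)))
  expect_gte(ok, 90)
})

test_that("two-sample t reproduces the printed sex comparison and degenerate cases", {
  # printed summary: female 1,583,561 +/- 225,978 (64) vs male
  # 1,706,232 +/- 151,086 (34), pooled form
  r <- two_sample_t(m1 = 1583561, s1 = 225978, n1 = 64,
                    m2 = 1706232, s2 = 151086, n2 = 34)
  expect_equal(round(r$p_value, 3), 0.005)
  ident <- two_sample_t(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(ident$auxiliary$t, 0)
  expect_equal(ident$p_value, 1)
  g1 <- c(0, 0, 0, 0) + withr::with_seed(1, rnorm(4, 0, 1e-9))
  g2 <- c(1, 1, 1, 1) + withr::with_seed(2, rnorm(4, 0, 1e-9))
  expect_lt(two_sample_t(g1, g2)$p_value, 1e-6)
  expect_tf_error(two_sample_t(1, c(1, 2)), "tf_sample_size_error")
  # sample mode agrees with the reference implementation
  a <- withr::with_seed(3, rnorm(30))
  b <- withr::with_seed(4, rnorm(25, 0.5))
  mine <- two_sample_t(a, b)
  ref <- t.test(a, b, var.equal = mine$auxiliary$var_equal)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("Mann-Whitney U uses exact enumeration for small untied samples", {
  # {1,2} vs {3,4}: U = 0; exact two-sided p = 2 * (1/6) = 1/3
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$estimate, 0)
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)
  expect_true(r$auxiliary$exact)
  # identical groups under average ranks: U = n1 n2 / 2
  ri <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ri$estimate, 4.5)
  # fully separated large groups
  rs <- mann_whitney(1:50, 101:150)
  expect_lt(rs$p_value, 1e-6)
  expect_false(rs$auxiliary$exact)   # n1*n2 > 400: normal approximation
  expect_tf_error(mann_whitney(numeric(0), 1:3), "tf_sample_size_error")
})

test_that("effect sizes match the printed values and hand cases", {
  expect_equal(round(cohen_dz(285052.34, 137012.73), 2), 2.08)
  expect_equal(cohen_dz(0, 3), 0)
  expect_equal(cohen_dz(2, 1), 2)   # differences {1,2,3}
  expect_tf_error(cohen_dz(1, 0), "tf_domain_error")
  expect_equal(round(cohen_d_pooled(1583561, 225978, 69,
                                    1706232, 151086, 29), 2), 0.59)
  expect_equal(cohen_d_pooled(5, 2, 10, 5, 2, 10), 0)
  expect_equal(cohen_d_pooled(0, 1, 20, 1, 1, 20), 1)
})

test_that("cohort validation reports offending rows", {
  co <- gen_cohort_table(cohort_sim_config(n = 10), seed = 1)
  expect_silent(validate_cohort(co))
  bad <- co
  bad$v_total[3] <- -5
  err <- tryCatch(validate_cohort(bad), error = function(e) e)
  expect_s3_class(err, "tf_schema_error")
  expect_match(conditionMessage(err), "row\\(s\\) 3")
  bad2 <- co[, setdiff(names(co), "v_superimposed")]
  expect_tf_error(validate_cohort(bad2), "tf_schema_error")
  bad3 <- co
  bad3$rtv[5] <- bad3$rtv[5] * 2
  expect_tf_error(validate_cohort(bad3), "tf_schema_error")
})

test_that("the analysis report runs the full battery deterministically", {
  co <- gen_cohort_table(cohort_sim_config(), seed = 42)
  rep1 <- analysis_report(co)
  rep2 <- analysis_report(co)
  expect_identical(rep1, rep2)
  expect_equal(rep1$sample$n, 98)
  expect_s3_class(rep1$correlations$overall, "stat_result")
  expect_true(all(c("test", "percent_of_mean", "cohen_dz", "achieved_power")
                  %in% names(rep1$paired$overall)))
  # percent-of-mean consistent with the paired estimate
  pm <- rep1$paired$overall$percent_of_mean
  expect_equal(unname(pm["estimate"]),
               round(100 * rep1$paired$overall$test$estimate /
                       mean(co$v_total), 2))
  # a 1-row cohort is schema-valid but collects sample-size errors
  r1 <- analysis_report(co[1, ])
  expect_false(is.null(r1$correlations$overall$error))
  expect_false(is.null(r1$paired$overall$error))
  expect_false(is.null(r1$comparisons$sex$v_total$error))
})
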
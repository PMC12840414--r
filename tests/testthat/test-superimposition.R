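test_that("outcome metrics implement the RTV and %SI formulas", {
  m <- compute_metrics(100, 80)
  expect_equal(m$RTV, 20)
  expect_equal(m$pct_SI, 80)
  # the reference cohort's mean volumes: RTV = 285,052.34
  m2 <- compute_metrics(1626120.79, 1341068.45)
  expect_equal(m2$RTV, 285052.34, tolerance = 1e-9)
  # perfect congruence
  m3 <- compute_metrics(12345.6, 12345.6)
  expect_equal(m3$RTV, 0)
  expect_equal(m3$pct_SI, 100)
  # identity holds exactly
  expect_identical(m2$V_superimposed + m2$RTV, m2$V_total)
  expect_tf_error(compute_metrics(100, 120), "tf_inconsistency")
  expect_tf_error(compute_metrics(0, 0), "tf_domain_error")
  expect_tf_error(compute_metrics(100, -1), "tf_domain_error")
})

test_that("the full protocol run conserves volume and is deterministic", {
  res <- cached_kappa_run(0.5)
  expect_s3_class(res, "superimposition_result")
  expect_identical(res$V_superimposed + res$RTV, res$V_total)
  expect_gte(res$pct_SI, 0)
  expect_lte(res$pct_SI, 100)
  expect_gt(res$V_total, 0)
  tooth <- cached_tooth()
  fc <- gen_face(face_shape_params(), tooth, kappa = 0.5)
  res2 <- run_superimposition(tooth$patch, fc$shell, tooth$landmarks,
                              fc$landmarks, NULL, pipeline_config())
  expect_identical(res2[c("V_total", "V_superimposed", "RTV", "pct_SI")],
                   res[c("V_total", "V_superimposed", "RTV", "pct_SI")])
})

test_that("%SI is invariant to whether scaling happens before or after extrusion setup", {
  tooth <- cached_tooth()
  fc <- gen_face(face_shape_params(), tooth, kappa = 0.75)
  res_a <- cached_kappa_run(0.75)
  # pre-scale the scan and landmarks; extrusion height scales with them and
  # the pipeline scale factor drops to 1
  s <- 15.56
  patch_s <- uniform_scale(tooth$patch, s)
  lm_s <- scale_landmarks(tooth$landmarks, s)
  cfg_b <- pipeline_config(scale = 1, extrusion = 6 * s)
  res_b <- run_superimposition(patch_s, fc$shell, lm_s, fc$landmarks, NULL,
                               cfg_b)
  expect_equal(res_b$pct_SI, res_a$pct_SI, tolerance = 1e-3)
  expect_equal(res_b$V_total, res_a$V_total, tolerance = 1e-6)
})

test_that("any cap depth beyond the tooth's posterior extent gives identical metrics", {
  tooth <- cached_tooth()
  fc <- gen_face(face_shape_params(), tooth, kappa = 0.5)
  res_default <- cached_kappa_run(0.5)
  res_deep <- run_superimposition(tooth$patch, fc$shell, tooth$landmarks,
                                  fc$landmarks, NULL,
                                  pipeline_config(cap_depth = 500))
  expect_equal(res_deep$pct_SI, res_default$pct_SI, tolerance = 1e-6)
})

test_that("stage failures are reported with the failing stage named", {
  tooth <- cached_tooth()
  fc <- gen_face(face_shape_params(), tooth, kappa = 0.5)
  err <- tryCatch(
    run_superimposition(tooth$patch, fc$shell, tooth$landmarks, fc$landmarks,
                        c(1, 500), pipeline_config()),
    error = function(e) e)
  expect_match(conditionMessage(err), "stage extract_patch")
})
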
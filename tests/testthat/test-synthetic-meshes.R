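test_that("the tooth patch matches its shape parameters", {
  params <- tooth_shape_params(width = 8.5, height = 11, sag = 1)
  tt <- gen_tooth(params, seed = 1)
  bb <- mesh_bbox(tt$patch)
  expect_equal(unname(bb["max", 1] - bb["min", 1]), 8.5, tolerance = 1e-9)
  expect_equal(unname(bb["max", 2] - bb["min", 2]), 11, tolerance = 1e-9)
  expect_equal(unname(bb["max", 3]), 1, tolerance = 1e-9)
  # landmarks sit on the outline at the edge midpoints
  expect_equal(tt$landmarks$incisal_midpoint[1:2], c(0, 0), tolerance = 1e-9)
  expect_equal(tt$landmarks$cervical_midpoint[1:2], c(0, 11), tolerance = 1e-9)
  expect_equal(abs(tt$landmarks$mesial_edge_midpoint[1]), 8.5 / 2,
               tolerance = 1e-9)
  # determinism
  tt2 <- gen_tooth(params, seed = 1)
  expect_identical(tt$patch$vertices, tt2$patch$vertices)
  tn <- gen_tooth(tooth_shape_params(noise_sd = 0.05), seed = 3)
  tn2 <- gen_tooth(tooth_shape_params(noise_sd = 0.05), seed = 3)
  expect_identical(tn$patch$vertices, tn2$patch$vertices)
  tn3 <- gen_tooth(tooth_shape_params(noise_sd = 0.05), seed = 4)
  expect_false(identical(tn$patch$vertices, tn3$patch$vertices))
})

test_that("a flat patch extrudes to exactly analytic area times height", {
  flat <- gen_tooth(tooth_shape_params(sag = 0), seed = 1)
  solid <- extrude_to_solid(flat$patch, 6)
  expect_equal(signed_volume(solid), flat$analytic_area * 6,
               tolerance = 1e-6)
})

test_that("tooth parameter validation catches unresolvable shapes", {
  expect_tf_error(tooth_shape_params(width = -1), "tf_parameter_error")
  expect_tf_error(tooth_shape_params(rounding = 5), "tf_parameter_error")
  expect_tf_error(tooth_shape_params(n_boundary = 15), "tf_parameter_error")
  # too few boundary samples to resolve the corner arcs
  expect_tf_error(tooth_shape_params(n_boundary = 16, rounding = 0.2),
                  "tf_parameter_error")
})

test_that("the facial shell embeds consistent landmarks and honours kappa", {
  tooth <- cached_tooth()
  fp <- face_shape_params()
  expect_tf_error(gen_face(fp, tooth, kappa = 1.5), "tf_domain_error")
  expect_tf_error(gen_face(fp, tooth, kappa = -0.1), "tf_domain_error")
  fc <- gen_face(fp, tooth, kappa = 0.5)
  # bizygomatic span = ratio x tooth width
  expect_equal(fc$landmarks$zygion_right[1] - fc$landmarks$zygion_left[1],
               15.56 * 8.5, tolerance = 1e-9)
  # midline landmarks at x = 0; glabella and pogonion at equal depth
  expect_equal(fc$landmarks$glabella[1], 0)
  expect_equal(fc$landmarks$glabella[3], fc$landmarks$pogonion[3],
               tolerance = 1e-9)
  # menton is the lowest landmark
  expect_lt(fc$landmarks$menton[2], fc$landmarks$pogonion[2])
  # determinism, and seeded noise changes the surface
  fc2 <- gen_face(fp, tooth, kappa = 0.5)
  expect_identical(fc$shell$vertices, fc2$shell$vertices)
  fn1 <- gen_face(fp, tooth, kappa = 0.5, noise_sd = 0.2, seed = 9)
  fn2 <- gen_face(fp, tooth, kappa = 0.5, noise_sd = 0.2, seed = 9)
  expect_identical(fn1$shell$vertices, fn2$shell$vertices)
  expect_false(identical(fn1$shell$vertices, fc$shell$vertices))
  # single boundary loop: closable into a solid
  expect_length(boundary_loops(fc$shell), 1)
})

test_that("subject fixtures are reproducible byte for byte", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  fx1 <- gen_subject_meshes(d1, kappa = 0.5, seed = 21)
  fx2 <- gen_subject_meshes(d2, kappa = 0.5, seed = 21)
  for (nm in c("tooth_stl", "face_stl", "tooth_landmarks", "face_landmarks")) {
    expect_identical(readBin(fx1$paths[[nm]], "raw", 1e7),
                     readBin(fx2$paths[[nm]], "raw", 1e7))
  }
  expect_equal(fx1$expected_band, fx2$expected_band)
})
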
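scaled_tooth_with_landmarks <- function() {
  if (is.null(fixture_env$scaled_tooth)) {
    tooth <- cached_tooth()
    solid <- cached_tooth_solid()
    ctr <- center_of_volume(solid)
    fixture_env$scaled_tooth <- list(
      mesh = uniform_scale(solid, 15.56, ctr),
      lm = scale_landmarks(tooth$landmarks, 15.56, ctr))
  }
  fixture_env$scaled_tooth
}

test_that("tooth alignment satisfies its stated postconditions exactly", {
  st <- scaled_tooth_with_landmarks()
  al <- align_tooth(st$mesh, st$lm)
  expect_lt(abs(al$landmarks$incisal_midpoint[1]), 1e-6)
  expect_lt(abs(al$landmarks$incisal_midpoint[3]), 1e-6)
  expect_lt(al$landmarks$incisal_midpoint[2], 0)   # incisal below the origin
  expect_lt(abs(al$landmarks$mesial_edge_midpoint[1] +
                al$landmarks$distal_edge_midpoint[1]), 1e-6)
  expect_lt(abs(al$landmarks$mesial_edge_midpoint[2] -
                al$landmarks$distal_edge_midpoint[2]), 1e-6)
  expect_lt(max(abs(center_of_volume(al$mesh))), 1e-6)
  # proper rigid transform, volume preserved
  expect_equal(det(al$transform$rotation), 1, tolerance = 1e-10)
  expect_equal(signed_volume(al$mesh), signed_volume(st$mesh),
               tolerance = 1e-9)
})

test_that("tooth alignment is idempotent and recovers a seeded perturbation", {
  st <- scaled_tooth_with_landmarks()
  al1 <- align_tooth(st$mesh, st$lm)
  # applying the op to its own output: identity within 1e-6
  al2 <- align_tooth(al1$mesh, al1$landmarks)
  expect_lt(max(abs(al2$transform$rotation - diag(3))), 1e-6)
  expect_lt(max(abs(al2$transform$translation)), 1e-6)
  # a known seeded rotation+translation is undone exactly
  tf <- withr::with_seed(11, rigid_transform(
    rotation_about_axis(rnorm(3), runif(1, 0, 2 * pi)), runif(3, -20, 20)))
  al3 <- align_tooth(apply_transform(st$mesh, tf),
                     transform_landmarks(st$lm, tf))
  expect_lt(max(abs(al3$mesh$vertices - al1$mesh$vertices)), 1e-6)
  comp <- compose_transforms(al3$transform, tf)
  expect_lt(max(abs(comp$rotation - al1$transform$rotation)), 1e-6)
  # determinism: identical inputs give bitwise-identical transforms
  al4 <- align_tooth(st$mesh, st$lm)
  expect_identical(al1$transform, al4$transform)
})

test_that("collinear tooth landmarks raise a degenerate-configuration error", {
  st <- scaled_tooth_with_landmarks()
  ctr <- center_of_volume(st$mesh)
  bad <- tooth_landmarks(incisal_midpoint = ctr + c(2, 0, 0),
                         mesial_edge_midpoint = ctr + c(3, 0, 0),
                         distal_edge_midpoint = ctr - c(1, 0, 0),
                         cervical_midpoint = ctr + c(0, 1, 0))
  expect_tf_error(align_tooth(st$mesh, bad), "tf_degenerate_configuration")
})

face_fixture <- function() {
  if (is.null(fixture_env$face_fix))
    fixture_env$face_fix <- gen_face(face_shape_params(), cached_tooth(),
                                     kappa = 0.5)
  fixture_env$face_fix
}

test_that("face alignment puts the midline in X = 0 and the facial line on Y", {
  ff <- face_fixture()
  al <- align_face(ff$shell, ff$landmarks)
  expect_lt(abs(al$landmarks$glabella[1]), 1e-6)
  expect_lt(abs(al$landmarks$labiale_superius[1]), 1e-6)
  gp <- al$landmarks$glabella - al$landmarks$pogonion
  gp <- gp / sqrt(sum(gp^2))
  expect_lt(max(abs(gp[c(1, 3)])), 1e-6)         # parallel to the Y axis
  expect_gt(gp[2], 0)                            # glabella above pogonion
  # origin at the area-weighted surface centroid
  expect_lt(max(abs(area_centroid(al$mesh))), 1e-6)
  # 30-degree seeded rotation about Z is inverted
  tf <- rigid_transform(rotation_about_axis(c(0, 0, 1), pi / 6), c(5, -3, 2))
  al2 <- align_face(apply_transform(ff$shell, tf),
                    transform_landmarks(ff$landmarks, tf))
  expect_lt(max(abs(al2$mesh$vertices - al$mesh$vertices)), 1e-6)
})

test_that("degenerate face landmark configurations are rejected", {
  ff <- face_fixture()
  lm <- ff$landmarks
  lm$pogonion <- lm$glabella
  expect_tf_error(align_face(ff$shell, lm), "tf_degenerate_configuration")
  expect_tf_error(
    face_landmarks(glabella = c(0, 1, 0), pogonion = c(0, 1, 0),
                   menton = c(0, -1, 0), labiale_superius = c(0, 0, 0),
                   zygion_left = c(-1, 0, 0), zygion_right = c(1, 0, 0),
                   alare_left = c(-0.5, 0, 0), alare_right = c(0.5, 0, 0)),
    "tf_degenerate_configuration")
})

test_that("tangency placement translates the tooth as specified", {
  ff <- face_fixture()
  st <- scaled_tooth_with_landmarks()
  tal <- align_tooth(st$mesh, st$lm)
  fal <- align_face(ff$shell, ff$landmarks)
  pl <- place_for_superimposition(fal$mesh, fal$landmarks, tal$mesh,
                                  tal$landmarks, mode = "zygion")
  expect_equal(pl$rotation, diag(3))
  # vertical least squares over the two tangency constraints
  t1 <- fal$landmarks$menton[2] - tal$landmarks$incisal_midpoint[2]
  t2 <- fal$landmarks$glabella[2] - tal$landmarks$cervical_midpoint[2]
  expect_equal(pl$translation[2], (t1 + t2) / 2, tolerance = 1e-12)
  expect_equal(attr(pl, "residuals")[["vertical"]], abs(t1 - t2) / 2,
               tolerance = 1e-12)
  # when the two constraints are simultaneously satisfiable, residual = 0
  lm0 <- fal$landmarks
  lm0$menton[2] <- tal$landmarks$incisal_midpoint[2] - 7
  lm0$glabella[2] <- tal$landmarks$cervical_midpoint[2] - 7
  pl0 <- place_for_superimposition(fal$mesh, lm0, tal$mesh, tal$landmarks)
  expect_equal(attr(pl0, "residuals")[["vertical"]], 0, tolerance = 1e-12)
  # translation equivariance: a +5 mm X shift of the tooth is cancelled
  shifted <- apply_transform(tal$mesh, rigid_transform(diag(3), c(5, 0, 0)))
  pl5 <- place_for_superimposition(fal$mesh, fal$landmarks, shifted,
                                   tal$landmarks)
  expect_equal(pl5$translation[1], pl$translation[1] - 5, tolerance = 1e-9)
  # zygion and alare tangency agree on a symmetric face
  pla <- place_for_superimposition(fal$mesh, fal$landmarks, tal$mesh,
                                   tal$landmarks, mode = "alare")
  expect_lt(abs(pla$translation[1] - pl$translation[1]), 1e-6)
  # missing tangency landmarks
  lmna <- fal$landmarks
  lmna$zygion_left <- NULL
  expect_tf_error(place_for_superimposition(fal$mesh, lmna, tal$mesh,
                                            tal$landmarks, mode = "zygion"),
                  "tf_missing_landmark")
})

test_that("landmark JSON sidecars round-trip and reject unknown names", {
  tooth <- cached_tooth()
  f <- withr::local_tempfile(fileext = ".json")
  write_landmarks(tooth$landmarks, f)
  back <- read_landmarks(f, "tooth")
  expect_equal(back$incisal_midpoint, tooth$landmarks$incisal_midpoint,
               tolerance = 1e-12)
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(incisal_midpoint = c(0, 0, 0), typo = c(1, 1, 1)),
                       bad)
  expect_tf_error(read_landmarks(bad, "tooth"), "tf_missing_landmark")
  ff <- face_fixture()
  f2 <- withr::local_tempfile(fileext = ".json")
  write_landmarks(ff$landmarks, f2)
  back2 <- read_landmarks(f2, "face")
  expect_equal(back2$menton, ff$landmarks$menton, tolerance = 1e-12)
})
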
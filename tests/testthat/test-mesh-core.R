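test_that("signed volume matches closed forms on primitive solids", {
  expect_equal(signed_volume(mesh_cube()), 1)
  expect_true(is_watertight(mesh_cube()))
  # regular tetrahedron: a^3 / (6 sqrt(2))
  expect_equal(signed_volume(mesh_tetrahedron(1)), 1 / (6 * sqrt(2)),
               tolerance = 1e-12)
  expect_equal(signed_volume(mesh_tetrahedron(2.5)), 2.5^3 / (6 * sqrt(2)),
               tolerance = 1e-12)
  # icosphere at >= 4 subdivisions within 0.5% of the sphere volume
  ic <- mesh_icosphere(1, 4)
  expect_lt(abs(signed_volume(ic) - 4 * pi / 3) / (4 * pi / 3), 0.005)
})

test_that("non-watertight meshes are rejected with the open edges named", {
  open_mesh <- mesh_cube()
  open_mesh$faces <- open_mesh$faces[-1, ]
  expect_false(is_watertight(open_mesh))
  err <- tryCatch(signed_volume(open_mesh), error = function(e) e)
  expect_s3_class(err, "tf_not_watertight")
  expect_match(conditionMessage(err), "open boundary edge")
  expect_gt(nrow(boundary_edges(open_mesh)), 0)
})

test_that("center of volume is exact on symmetric and compound solids", {
  expect_equal(center_of_volume(mesh_cube()), c(0.5, 0.5, 0.5),
               tolerance = 1e-12, ignore_attr = TRUE)
  # translation equivariance
  shifted <- apply_transform(mesh_cube(), rigid_transform(diag(3), c(10, 0, 0)))
  expect_equal(center_of_volume(shifted), c(10.5, 0.5, 0.5),
               tolerance = 1e-12, ignore_attr = TRUE)
  # L-shaped compound: volume-weighted mean of the two cuboid centroids,
  # (2*1 + 1*0.5)/3 = 2.5/3 in x and y
  ls <- l_shape_solid(1)
  expect_equal(signed_volume(ls), 3, tolerance = 1e-12)
  expect_equal(center_of_volume(ls), c(2.5 / 3, 2.5 / 3, -0.5),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("uniform scaling multiplies volume by s^3", {
  expect_equal(signed_volume(uniform_scale(mesh_cube(), 2)), 8,
               tolerance = 1e-12)
  # the protocol preset: 15.56^3 = 3767.287616 (computed independently)
  expect_equal(signed_volume(uniform_scale(mesh_cube(), 15.56)),
               3767.287616, tolerance = 1e-9)
  ident <- uniform_scale(mesh_cube(), 1)
  expect_identical(ident$vertices, mesh_cube()$vertices)
  expect_tf_error(uniform_scale(mesh_cube(), 0), "tf_domain_error")
  expect_tf_error(uniform_scale(mesh_cube(), -2), "tf_domain_error")
})

test_that("rigid transforms are validated and preserve metric structure", {
  expect_tf_error(rigid_transform(matrix(2 * diag(3), 3), c(0, 0, 0)),
                  "tf_domain_error")
  # reflections rejected
  refl <- diag(c(-1, 1, 1))
  expect_tf_error(rigid_transform(refl, c(0, 0, 0)), "tf_domain_error")
  cube <- mesh_cube()
  rot90 <- rigid_transform(rotation_about_axis(c(0, 0, 1), pi / 2))
  expect_equal(signed_volume(apply_transform(cube, rot90)), 1,
               tolerance = 1e-12)
  # translation then its inverse recovers vertices
  tr <- rigid_transform(diag(3), c(1, 2, 3))
  back <- apply_transform(apply_transform(cube, tr), invert_transform(tr))
  expect_equal(back$vertices, cube$vertices, tolerance = 1e-12)
  # seeded random rotation: pairwise distances distorted < 1e-9 relative
  tf <- withr::with_seed(42, rigid_transform(
    rotation_about_axis(rnorm(3), runif(1, 0, 2 * pi)), rnorm(3)))
  m <- random_convex_solid(7)
  m2 <- apply_transform(m, tf)
  d1 <- dist(m$vertices)
  d2 <- dist(m2$vertices)
  expect_lt(max(abs(d1 - d2) / pmax(d1, 1e-12)), 1e-9)
})

test_that("volume is invariant under rigid motion and scales as s^3 on random solids", {
  for (seed in 1:6) {
    m <- random_convex_solid(seed)
    v0 <- signed_volume(m)
    tf <- withr::with_seed(seed + 50L, rigid_transform(
      rotation_about_axis(rnorm(3), runif(1, 0, 2 * pi)), rnorm(3, 0, 5)))
    expect_equal(signed_volume(apply_transform(m, tf)), v0,
                 tolerance = 1e-9)
    s <- withr::with_seed(seed + 100L, runif(1, 0.3, 3))
    expect_equal(signed_volume(uniform_scale(m, s)), v0 * s^3,
                 tolerance = 1e-9)
  }
})

test_that("signed volume agrees with the voxel-column oracle on random convex solids", {
  for (seed in 1:8) {
    m <- random_convex_solid(seed)
    v_exact <- signed_volume(m)
    v_vox <- voxel_volume(m)   # pitch = bbox diagonal / 100
    expect_lt(abs(v_vox - v_exact) / v_exact, 0.01)
  }
})

test_that("vertex welding merges duplicates and drops degenerate faces", {
  cube <- mesh_cube()
  # duplicate the vertex set so every face gets private vertices
  dup <- triangle_mesh(cube$vertices[as.vector(t(cube$faces)), ],
                       matrix(seq_len(36), ncol = 3, byrow = TRUE))
  welded <- mesh_weld(dup)
  expect_equal(nrow(welded$vertices), 8)
  expect_equal(attr(welded, "diagnostics")$duplicates_merged, 28)
  expect_true(is_watertight(welded))
  expect_equal(signed_volume(welded), 1)
})
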
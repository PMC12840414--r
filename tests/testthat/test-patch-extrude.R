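test_that("patch extraction validates the selection and returns the sub-mesh", {
  g <- grid_mesh(6, 6)
  # a rectangular sub-grid with no smoothing is returned unchanged
  sel <- 1:24
  p <- extract_patch(g, sel, smoothing_iters = 0)
  expect_equal(nrow(p$faces), 24)
  used <- sort(unique(as.vector(g$faces[sel, ])))
  expect_equal(p$vertices, g$vertices[used, ], ignore_attr = TRUE)
  # disconnected islands rejected
  expect_tf_error(extract_patch(g, c(1, 50), smoothing_iters = 0),
                  "tf_invalid_selection")
  expect_tf_error(extract_patch(g, c(0, 1)), "tf_invalid_selection")
})

test_that("boundary smoothing strictly shortens a zig-zag boundary each pass", {
  g <- grid_mesh(8, 8)
  # displace boundary vertices alternately to make a zig-zag outline
  loops <- boundary_loops(g)
  loop <- loops[[1]]
  gz <- g
  gz$vertices[loop, 3] <- rep(c(0.1, -0.1), length.out = length(loop))
  p <- extract_patch(gz, seq_len(nrow(gz$faces)), smoothing_iters = 10)
  lens <- attr(p, "boundary_lengths")
  expect_length(lens, 11)
  expect_true(all(diff(lens) < 0))
})

test_that("extrusion of planar patches gives exact prisms", {
  sq <- triangle_mesh(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0),
                      rbind(c(1, 2, 3), c(1, 3, 4)))
  solid <- extrude_to_solid(sq, 6)
  expect_true(is_watertight(solid))
  expect_equal(signed_volume(solid), 6, tolerance = 1e-9)
  tri <- triangle_mesh(cbind(c(0, 1, 0), c(0, 0, 1), 0), rbind(c(1, 2, 3)))
  expect_equal(signed_volume(extrude_to_solid(tri, 6)), 3, tolerance = 1e-9)
  expect_tf_error(extrude_to_solid(sq, 0), "tf_domain_error")
  expect_tf_error(extrude_to_solid(sq, -1), "tf_domain_error")
})

test_that("curved-patch extrusion is watertight and matches the voxel oracle", {
  solid <- cached_tooth_solid()
  expect_true(is_watertight(solid))
  v_exact <- signed_volume(solid)
  expect_lt(abs(voxel_volume(solid) - v_exact) / v_exact, 0.01)
  # an extrusion deeper than the curvature radius folds and is rejected
  tooth <- cached_tooth()
  expect_tf_error(extrude_to_solid(tooth$patch, 40), "tf_extrusion_failure")
})

test_that("closing an open shell produces the expected solids", {
  # hemispherical shell capped at its equatorial plane: (2/3) pi r^3
  ic <- mesh_icosphere(1, 3)
  upper <- which(apply(matrix(ic$vertices[t(ic$faces), 3], ncol = 3,
                              byrow = TRUE), 1, min) >= -1e-9)
  shell <- extract_patch(ic, upper, smoothing_iters = 0)
  dome <- face_to_solid(shell, 0)
  expect_true(is_watertight(dome))
  expect_lt(abs(signed_volume(dome) - 2 * pi / 3) / (2 * pi / 3), 0.01)
  # planar square shell swept to depth d: volume = area * d
  sq <- triangle_mesh(cbind(c(0, 2, 2, 0), c(0, 0, 3, 3), 0),
                      rbind(c(1, 2, 3), c(1, 3, 4)))
  box <- face_to_solid(sq, 5)
  expect_equal(signed_volume(box), 2 * 3 * 5, tolerance = 1e-9)
  # a shell with a hole (two boundary loops) cannot be closed
  g <- grid_mesh(4, 4)
  # remove the central 2x2 block of cells -> an inner boundary loop
  inner <- c(11, 12, 13, 14, 19, 20, 21, 22)
  holed <- triangle_mesh(g$vertices, g$faces[-inner, ])
  expect_gt(length(boundary_loops(holed)), 1)
  expect_tf_error(face_to_solid(holed, 5), "tf_closure_error")
})
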
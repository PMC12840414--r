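# shared fixtures; heavy pipeline runs are cached so several test files can
# reuse them
fixture_env <- new.env()

# L-shaped prism: union of [0,2]x[0,1] and [0,1]x[1,2] footprints, height 1,
# extruded downward from z = 0
l_shape_solid <- function(h = 1) {
  v <- cbind(c(0, 2, 2, 1, 1, 0), c(0, 0, 1, 1, 2, 2), 0)
  f <- rbind(c(1, 2, 3), c(1, 3, 4), c(1, 4, 5), c(1, 5, 6))
  extrude_to_solid(triangle_mesh(v, f), h)
}

# planar triangulated grid on [0, nx*dx] x [0, ny*dx], z = 0
grid_mesh <- function(nx = 8, ny = 8, dx = 1) {
  v <- as.matrix(expand.grid(x = (0:nx) * dx, y = (0:ny) * dx))
  v <- cbind(v, 0)
  idx <- function(i, j) i + 1 + j * (nx + 1)
  f <- NULL
  for (j in 0:(ny - 1)) {
    for (i in 0:(nx - 1)) {
      f <- rbind(f,
                 c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
                 c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
    }
  }
  triangle_mesh(v, f)
}

# seeded random convex solid: transformed box or icosphere
random_convex_solid <- function(seed) {
  withr::with_seed(seed, {
    kind <- sample(c("box", "sphere"), 1)
    m <- if (kind == "box") {
      lo <- runif(3, -1, 0)
      mesh_box(lo, lo + runif(3, 0.5, 2))
    } else {
      mesh_icosphere(runif(1, 0.5, 1.5), 2)
    }
    m <- uniform_scale(m, runif(1, 0.6, 1.6))
    apply_transform(m, rigid_transform(
      rotation_about_axis(rnorm(3), runif(1, 0, 2 * pi)), runif(3, -0.3, 0.3)))
  })
}

# a pair of seeded solids with overlapping bounding boxes
random_solid_pair <- function(seed) {
  a <- random_convex_solid(seed)
  b <- random_convex_solid(seed + 1000L)
  ca <- center_of_volume(a)
  cb <- center_of_volume(b)
  shift <- withr::with_seed(seed + 2000L, runif(3, -0.4, 0.4))
  b <- apply_transform(b, rigid_transform(diag(3), ca - cb + shift))
  list(a = a, b = b)
}

# cached end-to-end superimposition for a given congruence
cached_kappa_run <- function(kappa) {
  key <- paste0("kappa_", kappa)
  hit <- fixture_env[[key]]
  if (!is.null(hit)) return(hit)
  tooth <- cached_tooth()
  fc <- gen_face(face_shape_params(), tooth, kappa = kappa)
  res <- run_superimposition(tooth$patch, fc$shell, tooth$landmarks,
                             fc$landmarks, NULL, pipeline_config())
  fixture_env[[key]] <- res
  res
}

cached_tooth <- function() {
  if (is.null(fixture_env$tooth)) fixture_env$tooth <- gen_tooth()
  fixture_env$tooth
}

cached_tooth_solid <- function() {
  if (is.null(fixture_env$tooth_solid)) {
    tooth <- cached_tooth()
    patch <- extract_patch(tooth$patch, seq_len(nrow(tooth$patch$faces)), 5)
    fixture_env$tooth_solid <- extrude_to_solid(patch, 6)
  }
  fixture_env$tooth_solid
}

expect_tf_error <- function(expr, class) {
  expect_error(expr, class = class)
}
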
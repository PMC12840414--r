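#' Tooth patch shape parameters
#'
#' Parameters of the synthetic buccal-surface patch of a maxillary central
#' incisor: a rounded-rectangle outline (mesio-distal width x
#' cervico-incisal height) carrying a smooth buccal convexity (`sag`).
#' Defaults approximate an adult central incisor crown: 8.5 mm wide,
#' 11 mm tall, 0.8 mm buccal sag.
#'
#' @param width mesio-distal width, mm.
#' @param height cervico-incisal height, mm.
#' @param sag buccal convexity depth at the patch centre, mm.
#' @param rounding corner radius of the outline, mm
#'   (< min(width, height)/2).
#' @param n_boundary boundary samples (multiple of 4).
#' @param n_rings radial rings of the triangulation.
#' @param noise_sd SD of seeded surface-normal noise on interior vertices,
#'   mm.
#' @export
tooth_shape_params <- function(width = 8.5, height = 11, sag = 0.8,
                               rounding = 1.5, n_boundary = 48, n_rings = 12,
                               noise_sd = 0) {
  if (width <= 0 || height <= 0) tf_stop("width and height must be positive", "tf_parameter_error")
  if (sag < 0) tf_stop("sag must be non-negative", "tf_parameter_error")
  if (rounding < 0 || rounding >= min(width, height) / 2)
    tf_stop("rounding must be in [0, min(width, height)/2)", "tf_parameter_error")
  if (n_boundary < 16 || n_boundary %% 4 != 0)
    tf_stop("n_boundary must be a multiple of 4, >= 16", "tf_parameter_error")
  if (n_rings < 3) tf_stop("n_rings must be >= 3", "tf_parameter_error")
  if (rounding > 0) {
    per <- 2 * (width + height) - 8 * rounding + 2 * pi * rounding
    per_corner <- n_boundary * (pi / 2 * rounding) / per
    if (per_corner < 2)
      tf_stop("boundary resolution too low to resolve the corner rounding",
              "tf_parameter_error")
  }
  structure(list(width = width, height = height, sag = sag,
                 rounding = rounding, n_boundary = n_boundary,
                 n_rings = n_rings, noise_sd = noise_sd),
            class = "tooth_shape_params")
}

# ordered CCW boundary of a rounded rectangle centred at the origin,
# starting at the bottom-edge midpoint; uniform arclength sampling
rounded_rect_boundary <- function(w, h, rc, nb) {
  hw <- w / 2; hh <- h / 2
  seg_len <- c(hw - rc,            # bottom-centre -> bottom-right start
               pi / 2 * rc,        # bottom-right corner
               h - 2 * rc,         # right edge
               pi / 2 * rc,        # top-right corner
               w - 2 * rc,         # top edge
               pi / 2 * rc,        # top-left corner
               h - 2 * rc,         # left edge
               pi / 2 * rc,        # bottom-left corner
               hw - rc)            # bottom-left -> bottom-centre
  cum <- cumsum(seg_len)
  per <- cum[9]
  point_at <- function(s) {
    s <- s %% per
    k <- findInterval(s, c(0, cum[-9]), rightmost.closed = FALSE)
    t <- s - c(0, cum)[k]
    switch(k,
      c(t, -hh),
      { a <- -pi / 2 + t / rc; c(hw - rc + rc * cos(a), -hh + rc + rc * sin(a)) },
      c(hw, -hh + rc + t),
      { a <- t / rc; c(hw - rc + rc * cos(a), hh - rc + rc * sin(a)) },
      c(hw - rc - t, hh),
      { a <- pi / 2 + t / rc; c(-hw + rc + rc * cos(a), hh - rc + rc * sin(a)) },
      c(-hw, hh - rc - t),
      { a <- pi + t / rc; c(-hw + rc + rc * cos(a), -hh + rc + rc * sin(a)) },
      c(-hw + rc + t, -hh))
  }
  t(vapply((seq_len(nb) - 1) / nb * per, point_at, numeric(2)))
}

# buccal convexity: elliptic paraboloid dome clamped at zero. No cross
# curvature, so the minimum curvature radius stays at (width/2)^2 / (2 sag)
# everywhere and the 6 mm inward offset of the extrusion cannot fold.
tooth_dome <- function(xi, eta) {
  pmax(0, 1 - pmin(1, xi^2 + eta^2))
}

# Triangulate a polar disk (centre vertex + nr rings of nb samples) with
# mirror-symmetric quad diagonals: each quad's diagonal follows the sign of
# its mean x, so a mesh built from an x-symmetric boundary is exactly
# mirror symmetric (keeping area centroids on the midline).
polar_disk_faces <- function(v2, nb, nr) {
  ring_idx <- function(i, j) 1 + (i - 1) * nb + (j - 1) %% nb + 1
  faces <- matrix(0L, nb + 2 * nb * (nr - 1), 3)
  for (j in seq_len(nb))
    faces[j, ] <- c(1L, ring_idx(1, j), ring_idx(1, j + 1))
  r <- nb
  for (i in 2:nr) {
    for (j in seq_len(nb)) {
      a <- ring_idx(i - 1, j); b <- ring_idx(i, j)
      cc <- ring_idx(i, j + 1); d <- ring_idx(i - 1, j + 1)
      if (v2[a, 1] + v2[b, 1] + v2[cc, 1] + v2[d, 1] >= 0) {
        faces[r + 1, ] <- c(a, b, cc)
        faces[r + 2, ] <- c(a, cc, d)
      } else {
        faces[r + 1, ] <- c(a, b, d)
        faces[r + 2, ] <- c(b, cc, d)
      }
      r <- r + 2
    }
  }
  faces
}

#' Generate a synthetic buccal tooth patch
#'
#' Builds a curved rounded-rectangle patch on a radial grid, with the four
#' protocol landmarks taken from the boundary (incisal and cervical edge
#' midpoints, mesial and distal proximal-edge midpoints). The patch lies
#' over `y` in `[0, height]` with the incisal edge at `y = 0` and the
#' buccal surface facing +z. Deterministic under `seed`.
#'
#' @param params a `tooth_shape_params`.
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @return list with `patch` (a `triangle_mesh` carrying the parameters as
#'   an attribute), `landmarks` (`tooth_landmarks`) and `analytic_area`
#'   (exact area of the flat outline polygon, mm^2).
#' @export
gen_tooth <- function(params = tooth_shape_params(), seed = 1) {
  stopifnot(inherits(params, "tooth_shape_params"))
  nb <- params$n_boundary; nr <- params$n_rings
  b <- rounded_rect_boundary(params$width, params$height, params$rounding, nb)
  nv <- 1 + nb * nr
  v2 <- matrix(0, nv, 2)
  for (i in seq_len(nr)) {
    v2[1 + (i - 1) * nb + seq_len(nb), ] <- b * (i / nr)
  }
  xi <- v2[, 1] / (params$width / 2)
  eta <- v2[, 2] / (params$height / 2)
  z <- params$sag * tooth_dome(xi, eta)
  if (params$noise_sd > 0) {
    interior <- seq_len(nv) <= 1 + nb * (nr - 1)
    z[interior] <- z[interior] + withr::with_seed(seed, stats::rnorm(
      sum(interior), 0, params$noise_sd))
  }
  verts <- cbind(v2[, 1], v2[, 2] + params$height / 2, z)
  faces <- polar_disk_faces(v2, nb, nr)
  patch <- triangle_mesh(verts, faces)
  attr(patch, "tooth_params") <- params
  outer0 <- 1 + nb * (nr - 1)
  lmk <- tooth_landmarks(
    incisal_midpoint = verts[outer0 + 1, ],
    mesial_edge_midpoint = verts[outer0 + nb / 4 + 1, ],
    distal_edge_midpoint = verts[outer0 + 3 * nb / 4 + 1, ],
    cervical_midpoint = verts[outer0 + nb / 2 + 1, ])
  # exact shoelace area of the flat outline polygon
  nb_x <- b[, 1]; nb_y <- b[, 2]
  j <- c(seq_len(nb)[-1], 1)
  area <- abs(sum(nb_x * nb_y[j] - nb_x[j] * nb_y)) / 2
  list(patch = patch, landmarks = lmk, analytic_area = area)
}
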
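#' Facial shell shape parameters
#'
#' Parameters of the synthetic facial scan: a smooth anterior shell over a
#' superelliptical outline with an ellipsoidal dome plus a nasal ridge,
#' carrying the protocol landmarks. The bizygomatic width is tied to the
#' tooth width through `ratio` (default 15.56, the mean
#' bizygomatic-to-tooth width ratio, which is also the tooth scaling
#' preset).
#'
#' @param width,height transverse / vertical extent of the shell outline, mm.
#' @param depth anterior depth of the facial dome at its centre, mm.
#' @param nose_height,nose_w,nose_h nasal ridge amplitude and Gaussian
#'   half-widths, mm.
#' @param boundary_exp superellipse exponent of the outline.
#' @param dome_power exponent shaping the dome falloff.
#' @param ratio bizygomatic-to-tooth width ratio (tooth scaling factor).
#' @param extrusion tooth extrusion height used when blending, mm.
#' @param smoothing_iters patch boundary smoothing passes used when
#'   blending (kept equal to the pipeline setting).
#' @param blend_margin width of the full-weight blend shelf outside the
#'   tooth footprint, mm (wider than the face mesh spacing).
#' @param n_boundary,n_rings mesh resolution.
#' @export
face_shape_params <- function(width = 164, height = 230, depth = 55,
                              nose_height = 18, nose_w = 11, nose_h = 28,
                              boundary_exp = 4, dome_power = 0.7,
                              ratio = 15.56, extrusion = 6,
                              smoothing_iters = 5, blend_margin = 12,
                              n_boundary = 64, n_rings = 20) {
  if (width <= 0 || height <= 0 || depth <= 0)
    tf_stop("width, height and depth must be positive", "tf_parameter_error")
  if (ratio <= 0) tf_stop("ratio must be positive", "tf_parameter_error")
  if (n_boundary < 16 || n_rings < 4)
    tf_stop("face mesh resolution too low", "tf_parameter_error")
  structure(list(width = width, height = height, depth = depth,
                 nose_height = nose_height, nose_w = nose_w, nose_h = nose_h,
                 boundary_exp = boundary_exp, dome_power = dome_power,
                 ratio = ratio, extrusion = extrusion,
                 smoothing_iters = smoothing_iters,
                 blend_margin = blend_margin,
                 n_boundary = n_boundary, n_rings = n_rings),
            class = "face_shape_params")
}

# superellipse "radius" coordinate: 1 on the outline, 0 at the centre
face_q <- function(params, x, y) {
  e <- params$boundary_exp
  abs(x / (params$width / 2))^e + abs(y / (params$height / 2))^e
}

face_base_z <- function(params, x, y) {
  q <- pmin(1, face_q(params, x, y))
  params$depth * (1 - q)^params$dome_power +
    params$nose_height * exp(-(x / params$nose_w)^2 - (y / params$nose_h)^2)
}

smoothstep <- function(t) {
  t <- pmin(1, pmax(0, t))
  t * t * (3 - 2 * t)
}

# place the scaled, aligned tooth solid against the face frame exactly the
# way the pipeline's tangency placement will, and return the anterior (top)
# surface submesh
place_tooth_for_blend <- function(tooth, params) {
  patch <- extract_patch(tooth$patch, seq_len(n_faces(tooth$patch)),
                         smoothing_iters = params$smoothing_iters)
  nf_top <- n_faces(patch)
  solid <- extrude_to_solid(patch, params$extrusion)
  ctr <- center_of_volume(solid)
  scaled <- uniform_scale(solid, params$ratio, ctr)
  lm_s <- scale_landmarks(tooth$landmarks, params$ratio, ctr)
  al <- align_tooth(scaled, lm_s)
  lmpos <- face_landmark_positions(params, tooth)
  ty <- mean(c(lmpos$menton[2] - al$landmarks$incisal_midpoint[2],
               lmpos$glabella[2] - al$landmarks$cervical_midpoint[2]))
  tx <- -mean(range(al$mesh$vertices[, 1]))
  placed <- apply_transform(al$mesh, rigid_transform(diag(3), c(tx, ty, 0)))
  # depth tangency: anterior-most tooth vertex to the anterior-most base
  # point (the dome-plus-nose peak at the origin)
  zmax_face <- face_base_z(params, 0, 0)
  tz <- zmax_face - max(placed$vertices[, 3])
  placed <- apply_transform(placed, rigid_transform(diag(3), c(0, 0, tz)))
  top <- list(vertices = placed$vertices,
              faces = placed$faces[seq_len(nf_top), , drop = FALSE])
  list(top_vertices = top$vertices, top_faces = top$faces, solid = placed)
}

face_landmark_positions <- function(params, tooth) {
  tw <- attr(tooth$patch, "tooth_params")$width
  list(glabella = c(0, 60), pogonion = c(0, -60), menton = c(0, -100),
       labiale_superius = c(0, -45),
       zygion_left = c(-params$ratio * tw / 2, 5),
       zygion_right = c(params$ratio * tw / 2, 5),
       alare_left = c(-17, -25), alare_right = c(17, -25),
       nasion = c(0, 70))
}

#' Generate a synthetic facial shell with landmarks
#'
#' Builds a smooth anterior facial shell and blends its surface toward the
#' scaled tooth surface, placed exactly as the superimposition pipeline
#' will place it, with weight `kappa` (the congruence parameter):
#' `kappa = 1` with zero noise makes the mid-face coincide with the tooth
#' surface, `kappa = 0` leaves the pure base face. Landmark coordinates are
#' taken on the unblended base shell, with glabella and pogonion at equal
#' depth and all midline landmarks at x = 0, so the landmark-based
#' alignment of the generated face is an exact translation.
#'
#' @param params a `face_shape_params`.
#' @param tooth result of [gen_tooth()] (the patch carries its shape
#'   parameters; scaling by `params$ratio` happens internally).
#' @param kappa congruence in `[0, 1]`.
#' @param noise_sd SD of seeded vertical surface noise, mm.
#' @param seed integer seed for the noise.
#' @return list with `shell` (`triangle_mesh`), `landmarks`
#'   (`face_landmarks`) and `placed_tooth` (the tooth solid in the face
#'   frame, for diagnostics).
#' @export
gen_face <- function(params = face_shape_params(), tooth, kappa,
                     noise_sd = 0, seed = 1) {
  stopifnot(inherits(params, "face_shape_params"))
  if (!is.numeric(kappa) || length(kappa) != 1 || is.na(kappa) ||
      kappa < 0 || kappa > 1)
    tf_stop("kappa must be in [0, 1]", "tf_domain_error")
  nb <- params$n_boundary; nr <- params$n_rings
  theta <- (seq_len(nb) - 1) / nb * 2 * pi
  e <- params$boundary_exp
  a <- params$width / 2; b2 <- params$height / 2
  rr <- (abs(cos(theta) / a)^e + abs(sin(theta) / b2)^e)^(-1 / e)
  bnd <- cbind(rr * cos(theta), rr * sin(theta))
  nv <- 1 + nb * nr
  v2 <- matrix(0, nv, 2)
  for (i in seq_len(nr)) v2[1 + (i - 1) * nb + seq_len(nb), ] <- bnd * (i / nr)
  x <- v2[, 1]; y <- v2[, 2]
  base <- face_base_z(params, x, y)

  pl <- place_tooth_for_blend(tooth, params)
  zt <- surface_z_max_cpp(pl$top_vertices, pl$top_faces, x, y)
  defined <- !is.na(zt)
  # Constant extension of the tooth surface outside its footprint. The
  # blend keeps full weight over a margin shelf wider than the face mesh
  # spacing, so triangles straddling the footprint edge interpolate at
  # tooth-edge height instead of cutting the corner, then decays.
  margin <- params$blend_margin
  w <- numeric(nv)
  w[defined] <- 1
  if (any(!defined)) {
    tv <- pl$top_vertices[unique(as.vector(pl$top_faces)), , drop = FALSE]
    for (i in which(!defined)) {
      d2 <- (tv[, 1] - x[i])^2 + (tv[, 2] - y[i])^2
      j <- which.min(d2)
      zt[i] <- tv[j, 3]
      d <- sqrt(d2[j])
      w[i] <- if (d <= margin) 1 else exp(-((d - margin) / 8)^2)
    }
  }
  # kill the blend before the shell outline so the boundary stays on the base
  qw <- smoothstep((0.97 - face_q(params, x, y)) / 0.12)
  w <- w * qw
  # keep the nasal ridge out of the blend: the face then retains a fixed
  # anterior-most point (the nose tip) at every kappa, so the depth-tangency
  # placement is congruence-independent and %SI is monotone in kappa. The
  # nose sits over the central footprint, where the facial dome lies well
  # anterior of the tooth surface, so this does not create overlap deficit.
  qn <- (x / params$nose_w)^2 + (y / params$nose_h)^2
  w <- w * (1 - exp(-qn^2))
  z <- base + kappa * w * (zt - base)
  if (noise_sd > 0)
    z <- z + withr::with_seed(seed, stats::rnorm(nv, 0, noise_sd))
  shell <- triangle_mesh(cbind(x, y, z), polar_disk_faces(v2, nb, nr))
  lmpos <- face_landmark_positions(params, tooth)
  lm3 <- lapply(lmpos, function(p) c(p, face_base_z(params, p[1], p[2])))
  lm <- face_landmarks(
    glabella = lm3$glabella, pogonion = lm3$pogonion, menton = lm3$menton,
    labiale_superius = lm3$labiale_superius,
    zygion_left = lm3$zygion_left, zygion_right = lm3$zygion_right,
    alare_left = lm3$alare_left, alare_right = lm3$alare_right,
    nasion = lm3$nasion)
  attr(shell, "kappa") <- kappa
  list(shell = shell, landmarks = lm, placed_tooth = pl$solid)
}
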
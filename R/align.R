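# Landmark-based alignment of the tooth solid and the facial shell into a
# common reference frame: X transverse (mesio-distal), Y vertical
# (cervico-incisal / facial midline, up positive), Z anteroposterior
# (anterior positive), all right-handed.

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) tf_stop("degenerate direction (zero length)",
                         "tf_degenerate_configuration")
  v / n
}

#' Align the tooth solid to the reference frame
#'
#' Centres the solid at its centre of volume and rotates it so the incisal
#' midpoint lies on the vertical axis (below the origin, X = Z = 0) and the
#' mesial/distal edge midpoints sit symmetrically about the midline (equal
#' |X| of opposite sign, equal Y) with the buccal surface facing +Z. The
#' rotation is exact when the landmark set is consistent (incisal-cervical
#' axis perpendicular to the mesio-distal chord); residual asymmetry of an
#' inconsistent set is reported, not absorbed.
#'
#' @param solid watertight `triangle_mesh` (the extruded, scaled tooth).
#' @param lm `tooth_landmarks` in the same frame as `solid`.
#' @return list with `transform` (the applied `rigid_transform`), `mesh`,
#'   `landmarks` and `residuals`.
#' @export
align_tooth <- function(solid, lm) {
  stopifnot(inherits(lm, "tooth_landmarks"))
  ctr <- center_of_volume(solid)
  i <- lm$incisal_midpoint - ctr
  m <- lm$mesial_edge_midpoint - ctr
  d <- lm$distal_edge_midpoint - ctr
  md <- m - d
  if (sqrt(sum(row_cross(matrix(i, 1), matrix(md, 1))^2)) < 1e-9 * sqrt(sum(i^2)) * sqrt(sum(md^2)))
    tf_stop("landmarks are collinear: reference plane undefined",
            "tf_degenerate_configuration")
  yhat <- unit(-i)                                   # incisal points down
  xhat <- unit(md - sum(md * yhat) * yhat)           # mesio-distal, in-plane
  zhat <- as.numeric(row_cross(matrix(xhat, 1), matrix(yhat, 1)))
  # make +Z the buccal (landmark) side
  lmc <- (lm$incisal_midpoint + lm$mesial_edge_midpoint +
          lm$distal_edge_midpoint + lm$cervical_midpoint) / 4 - ctr
  if (sum(zhat * lmc) < 0) {
    xhat <- -xhat
    zhat <- -zhat
  }
  R <- rbind(xhat, yhat, zhat)
  dimnames(R) <- NULL
  tf <- rigid_transform(R, as.numeric(-R %*% ctr))
  out_mesh <- apply_transform(solid, tf)
  out_lm <- transform_landmarks(lm, tf)
  residuals <- c(
    incisal_off_axis = max(abs(out_lm$incisal_midpoint[c(1, 3)])),
    proximal_y_asym = abs(out_lm$mesial_edge_midpoint[2] -
                          out_lm$distal_edge_midpoint[2]),
    proximal_x_asym = abs(out_lm$mesial_edge_midpoint[1] +
                          out_lm$distal_edge_midpoint[1]))
  list(transform = tf, mesh = out_mesh, landmarks = out_lm,
       residuals = residuals)
}

#' Align the facial shell to the reference frame
#'
#' Centres the shell at its area-weighted surface centroid and rotates it so
#' the glabella-to-pogonion direction is vertical (parallel to -Y) and both
#' glabella and labiale superius lie in the X = 0 midsagittal plane, anterior
#' surface facing +Z. Exact for a symmetric face whose midline landmarks and
#' surface centroid are coplanar; residuals are reported otherwise.
#'
#' @param face open `triangle_mesh` facial shell.
#' @param lm `face_landmarks` in the same frame as `face`.
#' @return list with `transform`, `mesh`, `landmarks`, `residuals`.
#' @export
align_face <- function(face, lm) {
  stopifnot(inherits(lm, "face_landmarks"))
  ctr <- area_centroid(face)
  g <- lm$glabella - ctr
  ls <- lm$labiale_superius - ctr
  gp <- lm$glabella - lm$pogonion
  if (sqrt(sum(gp^2)) < 1e-9)
    tf_stop("glabella and pogonion coincide", "tf_degenerate_configuration")
  nrm <- as.numeric(row_cross(matrix(g, 1), matrix(ls, 1)))
  if (sqrt(sum(nrm^2)) < 1e-9)
    tf_stop("glabella, labiale superius and surface centroid are collinear",
            "tf_degenerate_configuration")
  xhat <- unit(nrm)
  yhat <- unit(gp - sum(gp * xhat) * xhat)           # glabella above pogonion
  zhat <- as.numeric(row_cross(matrix(xhat, 1), matrix(yhat, 1)))
  lmc <- Reduce(`+`, unclass(lm)[FACE_LANDMARK_REQUIRED]) / 8 - ctr
  if (sum(zhat * lmc) < 0) {
    xhat <- -xhat
    zhat <- -zhat
  }
  R <- rbind(xhat, yhat, zhat)
  dimnames(R) <- NULL
  tf <- rigid_transform(R, as.numeric(-R %*% ctr))
  out_mesh <- apply_transform(face, tf)
  out_lm <- transform_landmarks(lm, tf)
  gp_out <- out_lm$glabella - out_lm$pogonion
  residuals <- c(
    midline_glabella = abs(out_lm$glabella[1]),
    midline_labiale = abs(out_lm$labiale_superius[1]),
    vertical_angle = acos(min(1, abs(unit(gp_out)[2]))))
  list(transform = tf, mesh = out_mesh, landmarks = out_lm,
       residuals = residuals)
}

#' Place the aligned tooth on the aligned face
#'
#' Pure translation (the rotations are fixed by the two preceding
#' alignments) implementing the tangency protocol: vertically, the incisal
#' midpoint is taken to the menton level and the cervical midpoint to the
#' glabella level as closely as one translation allows (least squares over
#' the two constraints, residual reported); transversely, the tooth's
#' mesial/distal extremes are centred on the zygion or alare span; in depth,
#' the tooth's anterior-most vertex is brought to the face's anterior-most
#' surface point (plus `z_offset`).
#'
#' @param face_aligned aligned facial shell (`triangle_mesh`).
#' @param face_lm aligned `face_landmarks`.
#' @param tooth_aligned aligned tooth solid (`triangle_mesh`).
#' @param tooth_lm aligned `tooth_landmarks`.
#' @param mode `"zygion"` or `"alare"`: the transverse tangency pair.
#' @param z_offset extra anteroposterior displacement in mm (0 places the
#'   tooth tangent to the face's anterior-most point).
#' @return a `rigid_transform` (identity rotation) for the tooth, with
#'   attribute `residuals`.
#' @export
place_for_superimposition <- function(face_aligned, face_lm, tooth_aligned,
                                      tooth_lm, mode = c("zygion", "alare"),
                                      z_offset = 0) {
  mode <- match.arg(mode)
  pair <- if (mode == "zygion") c("zygion_left", "zygion_right")
          else c("alare_left", "alare_right")
  if (is.null(face_lm[[pair[1]]]) || is.null(face_lm[[pair[2]]]))
    tf_stop(paste("landmarks required for mode", mode, "are missing"),
            "tf_missing_landmark")
  # vertical: least-squares over incisal->menton and cervical->glabella
  t1 <- face_lm$menton[2] - tooth_lm$incisal_midpoint[2]
  t2 <- face_lm$glabella[2] - tooth_lm$cervical_midpoint[2]
  ty <- (t1 + t2) / 2
  vert_residual <- abs(t1 - t2) / 2
  # transverse: centre the tooth x-extremes on the tangency span
  span_mid <- (face_lm[[pair[1]]][1] + face_lm[[pair[2]]][1]) / 2
  tooth_mid <- (min(tooth_aligned$vertices[, 1]) +
                max(tooth_aligned$vertices[, 1])) / 2
  tx <- span_mid - tooth_mid
  # depth: anterior-most tooth vertex to anterior-most face point
  tz <- max(face_aligned$vertices[, 3]) - max(tooth_aligned$vertices[, 3]) +
    z_offset
  tf <- rigid_transform(diag(3), c(tx, ty, tz))
  attr(tf, "residuals") <- c(vertical = vert_residual)
  tf
}
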
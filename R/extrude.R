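#' Extract a surface patch from a mesh
#'
#' Returns the sub-mesh of the selected faces after validating that the
#' selection is one edge-connected component whose boundary is a single
#' closed loop, then smooths the boundary curve in place (interior vertices
#' untouched) with damped Laplacian passes, emulating an "optimized and
#' smoothed" selection boundary.
#'
#' @param mesh source `triangle_mesh`.
#' @param sel integer vector of face indices of `mesh`.
#' @param smoothing_iters number of boundary Laplacian iterations.
#' @param lambda damping of each pass (0-1).
#' @return an open `triangle_mesh`; attribute `boundary_lengths` records the
#'   boundary perimeter after each pass (element 1 = before smoothing).
#' @export
extract_patch <- function(mesh, sel, smoothing_iters = 5, lambda = 0.5) {
  sel <- unique(as.integer(sel))
  if (length(sel) == 0 || any(sel < 1) || any(sel > n_faces(mesh)))
    tf_stop("selection indices out of range", "tf_invalid_selection")
  f <- mesh$faces[sel, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  remap <- match(f, used)
  patch <- triangle_mesh(mesh$vertices[used, , drop = FALSE],
                         matrix(remap, ncol = 3))
  # one edge-connected component
  if (n_faces(patch) > 1) {
    comp <- patch_components(patch)
    if (length(unique(comp)) > 1)
      tf_stop("selection is not edge-connected (disjoint islands)",
              "tf_invalid_selection")
  }
  loops <- boundary_loops(patch)
  if (length(loops) != 1)
    tf_stop(sprintf("selection boundary must be a single closed loop (found %d)",
                    length(loops)), "tf_invalid_selection")
  loop <- loops[[1]]
  lengths <- boundary_length(patch$vertices, loop)
  area0 <- surface_area(patch)
  if (smoothing_iters > 0) {
    nb <- length(loop)
    prev <- c(nb, seq_len(nb - 1))
    nxt <- c(seq_len(nb)[-1], 1)
    for (it in seq_len(smoothing_iters)) {
      b <- patch$vertices[loop, , drop = FALSE]
      target <- (b[prev, , drop = FALSE] + b[nxt, , drop = FALSE]) / 2
      patch$vertices[loop, ] <- b + lambda * (target - b)
      lengths <- c(lengths, boundary_length(patch$vertices, loop))
      area1 <- surface_area(patch)
      if (abs(area1 - area0) > 0.05 * area0)
        warning("boundary smoothing pass changed patch area by more than 5%")
      area0 <- area1
    }
  }
  attr(patch, "boundary_lengths") <- lengths
  attr(patch, "boundary_loop") <- loops[[1]]
  patch
}

patch_components <- function(patch) {
  nf <- n_faces(patch)
  he <- half_edges(patch)
  k <- edge_keys(he)
  face_of <- rep(seq_len(nf), 3)
  pairs <- split(face_of, k)
  nbr <- vector("list", nf)
  for (p in pairs) {
    if (length(p) >= 2) {
      for (i in p) nbr[[i]] <- c(nbr[[i]], setdiff(p, i))
    }
  }
  comp <- rep(NA_integer_, nf)
  cid <- 0L
  for (s in seq_len(nf)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (j in nbr[[cur]]) {
        if (is.na(comp[j])) { comp[j] <- cid; queue <- c(queue, j) }
      }
    }
  }
  comp
}

boundary_length <- function(v, loop) {
  b <- v[loop, , drop = FALSE]
  d <- b - b[c(seq_len(nrow(b))[-1], 1), , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

# area-weighted vertex normals
vertex_normals <- function(mesh) {
  fc <- face_corners(mesh)
  fn <- row_cross(fc$b - fc$a, fc$c - fc$a)   # length = 2 * area
  vn <- matrix(0, n_vertices(mesh), 3)
  for (k in 1:3) {
    m <- rowsum(fn, group = mesh$faces[, k], reorder = FALSE)
    vn[as.integer(rownames(m)), ] <- vn[as.integer(rownames(m)), ] + m
  }
  len <- sqrt(rowSums(vn^2))
  len[len == 0] <- 1
  vn / len
}

# regularise an offset direction field: average each vertex normal with its
# 1-ring mean and renormalise (identity for a constant field, so planar
# prisms stay exact)
smooth_normals <- function(mesh, vn, iters = 2) {
  if (iters < 1) return(vn)
  he <- half_edges(mesh)
  # unique undirected edges: the 1-ring stencil must not depend on face
  # orientation (a directed stencil drops one neighbour at the boundary)
  und <- he[!duplicated(edge_keys(he)), , drop = FALSE]
  both <- rbind(und, und[, c(2, 1), drop = FALSE])
  cnt <- as.numeric(table(factor(both[, 1], levels = seq_len(nrow(vn)))))
  for (it in seq_len(iters)) {
    acc <- rowsum(vn[both[, 2], , drop = FALSE], group = both[, 1],
                  reorder = TRUE)
    idx <- as.integer(rownames(acc))
    mean_n <- vn
    mean_n[idx, ] <- acc / pmax(1, cnt[idx])
    vn <- vn + mean_n
    len <- sqrt(rowSums(vn^2))
    len[len == 0] <- 1
    vn <- vn / len
  }
  vn
}

#' Extrude an open patch to a watertight solid
#'
#' Offsets every vertex by `h` along the inward mean surface normal (away
#' from the viewing/buccal side), then stitches the original patch, the
#' offset copy and a side wall along the single boundary loop. For a planar
#' patch the result is a prism of volume `area * h`.
#'
#' @param patch open `triangle_mesh` with exactly one boundary loop,
#'   wound so its normals point outward/anterior.
#' @param h extrusion height in mm (the protocol preset is 6 mm).
#' @return watertight `triangle_mesh`.
#' @export
extrude_to_solid <- function(patch, h) {
  if (!is.numeric(h) || length(h) != 1 || h <= 0)
    tf_stop("extrusion height must be positive", "tf_domain_error")
  loops <- boundary_loops(patch)
  if (length(loops) != 1)
    tf_stop(sprintf("patch must have exactly one boundary loop (found %d)",
                    length(loops)), "tf_invalid_selection")
  loop <- loops[[1]]
  vn <- smooth_normals(patch, vertex_normals(patch))
  nv <- n_vertices(patch)
  bottom_v <- patch$vertices - h * vn
  # Reject offsets that fold the surface over itself: an offset deeper than
  # the local curvature radius flips triangles with substantial area. A few
  # micro-slivers can flip numerically on any curved mesh, so the criterion
  # is the total flipped offset area relative to the patch area (> 0.1%).
  fc_top <- face_corners(patch)
  top_n <- row_cross(fc_top$b - fc_top$a, fc_top$c - fc_top$a)
  bot <- triangle_mesh(bottom_v, patch$faces)
  fc_bot <- face_corners(bot)
  bot_n <- row_cross(fc_bot$b - fc_bot$a, fc_bot$c - fc_bot$a)
  flipped <- rowSums(top_n * bot_n) <= 0
  flipped_frac <- sum(sqrt(rowSums(bot_n[flipped, , drop = FALSE]^2))) /
    sum(sqrt(rowSums(top_n^2)))
  if (flipped_frac > 1e-3)
    tf_stop(sprintf(
      "extrusion folds the offset surface (h too large for curvature; flipped area fraction %.2g)",
      flipped_frac), "tf_extrusion_failure")
  top_f <- patch$faces
  bot_f <- patch$faces[, c(1, 3, 2), drop = FALSE] + nv
  nb <- length(loop)
  a <- loop
  b <- loop[c(seq_len(nb)[-1], 1)]
  # each wall quad is fanned through its centre point: frame-independent
  # and mirror-symmetric, so the solid inherits the patch's symmetry in
  # any pose
  qc <- (patch$vertices[a, , drop = FALSE] + patch$vertices[b, , drop = FALSE] +
         bottom_v[a, , drop = FALSE] + bottom_v[b, , drop = FALSE]) / 4
  verts <- rbind(patch$vertices, bottom_v, qc)
  m <- 2 * nv + seq_len(nb)
  wall <- rbind(cbind(m, a, a + nv), cbind(m, a + nv, b + nv),
                cbind(m, b + nv, b), cbind(m, b, a))
  solid <- triangle_mesh(verts, rbind(top_f, bot_f, wall))
  if (signed_volume(solid, check_watertight = FALSE) < 0)
    solid$faces <- solid$faces[, c(1, 3, 2)]
  if (!is_watertight(solid))
    tf_stop("extrusion produced a non-watertight solid", "tf_extrusion_failure")
  solid
}

#' Close an open shell into a watertight solid
#'
#' Sweeps the shell's single outer boundary straight back to the plane
#' `z = -cap_depth` and caps the swept outline with a fan, leaving the
#' anterior surface untouched. This turns a facial scan (an open shell)
#' into a solid operand for Boolean volumetry.
#'
#' @param shell open `triangle_mesh`, normals anterior (+z).
#' @param cap_depth depth of the closing plane below z = 0 (mm); must lie
#'   at or behind every boundary vertex.
#' @return watertight `triangle_mesh`.
#' @export
face_to_solid <- function(shell, cap_depth) {
  if (!is.numeric(cap_depth) || length(cap_depth) != 1 || !is.finite(cap_depth))
    tf_stop("cap_depth must be a finite number", "tf_domain_error")
  loops <- boundary_loops(shell)
  if (length(loops) != 1)
    tf_stop(sprintf("shell must have a single outer boundary (found %d loops)",
                    length(loops)), "tf_closure_error")
  loop <- loops[[1]]
  zcap <- -cap_depth
  bz <- shell$vertices[loop, 3]
  if (any(bz < zcap - 1e-9))
    tf_stop("cap plane must lie at or behind every boundary vertex",
            "tf_domain_error")
  nv <- n_vertices(shell)
  nb <- length(loop)
  proj <- cbind(shell$vertices[loop, 1], shell$vertices[loop, 2], zcap)
  center <- c(colMeans(proj[, 1:2, drop = FALSE]), zcap)
  a <- loop
  b <- loop[c(seq_len(nb)[-1], 1)]
  pa <- nv + seq_len(nb)
  pb <- nv + c(seq_len(nb)[-1], 1)
  # wall quads fanned through their centre points (frame-independent,
  # mirror-symmetric split)
  ord <- match(b, loop)
  qc <- (shell$vertices[a, , drop = FALSE] + shell$vertices[b, , drop = FALSE] +
         proj[match(a, loop), , drop = FALSE] + proj[ord, , drop = FALSE]) / 4
  verts <- rbind(shell$vertices, proj, matrix(center, 1), qc)
  m <- nv + nb + 1L + seq_len(nb)
  wall <- rbind(cbind(m, a, pa), cbind(m, pa, pb), cbind(m, pb, b),
                cbind(m, b, a))
  cidx <- nv + nb + 1L
  cap <- cbind(cidx, pb, pa)
  faces <- rbind(shell$faces, wall, cap)
  # drop degenerate wall triangles (boundary vertex already on the cap
  # plane): weld, then remove faces with area below a scale-aware floor
  solid <- triangle_mesh(verts, faces)
  solid <- mesh_weld(solid, tol = 1e-9)
  bb <- mesh_bbox(solid)
  diag2 <- sum((bb["max", ] - bb["min", ])^2)
  solid$faces <- solid$faces[face_areas(solid) > 1e-14 * diag2, , drop = FALSE]
  if (signed_volume(solid, check_watertight = FALSE) < 0)
    solid$faces <- solid$faces[, c(1, 3, 2)]
  if (!is_watertight(solid))
    tf_stop("closure produced a non-watertight solid", "tf_closure_error")
  solid
}
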
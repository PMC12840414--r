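#' Triangle mesh
#'
#' A minimal indexed triangle mesh: an `n x 3` matrix of vertex coordinates
#' (mm) and an `m x 3` integer matrix of 1-based vertex indices with
#' counter-clockwise (outward) winding. This is the carrier for tooth
#' patches, extruded solids and facial shells throughout the package.
#'
#' @param vertices numeric matrix, one row per vertex (x, y, z) in mm.
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @return an object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- matrix(as.numeric(vertices), ncol = 3,
                     dimnames = list(NULL, c("x", "y", "z")))
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) > 0) {
    if (any(!is.finite(vertices))) tf_stop("non-finite vertex coordinates", "tf_domain_error")
    if (min(faces) < 1 || max(faces) > nrow(vertices))
      tf_stop("face indices out of range", "tf_domain_error")
  }
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh: %d vertices, %d faces%s>\n",
              nrow(x$vertices), nrow(x$faces),
              if (isTRUE(is_watertight(x))) ", watertight" else ""))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)
n_faces <- function(mesh) nrow(mesh$faces)

#' Axis-aligned bounding box
#' @param mesh a `triangle_mesh`.
#' @return 2 x 3 matrix with rows `min`, `max`.
#' @export
mesh_bbox <- function(mesh) {
  rbind(min = apply(mesh$vertices, 2, min), max = apply(mesh$vertices, 2, max))
}

face_corners <- function(mesh) {
  list(a = mesh$vertices[mesh$faces[, 1], , drop = FALSE],
       b = mesh$vertices[mesh$faces[, 2], , drop = FALSE],
       c = mesh$vertices[mesh$faces[, 3], , drop = FALSE])
}

row_cross <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

face_areas <- function(mesh) {
  fc <- face_corners(mesh)
  cr <- row_cross(fc$b - fc$a, fc$c - fc$a)
  0.5 * sqrt(rowSums(cr^2))
}

#' Total surface area of a mesh (mm^2)
#' @param mesh a `triangle_mesh`.
#' @export
surface_area <- function(mesh) sum(face_areas(mesh))

#' Area-weighted surface centroid
#'
#' Centroid of the surface (the "center of mass" of a thin shell), used as
#' the origin convention for facial scans.
#' @param mesh a `triangle_mesh`.
#' @return length-3 numeric.
#' @export
area_centroid <- function(mesh) {
  fc <- face_corners(mesh)
  ar <- face_areas(mesh)
  ctr <- (fc$a + fc$b + fc$c) / 3
  colSums(ctr * ar) / sum(ar)
}

# directed edge table: one row per half-edge (from, to)
half_edges <- function(mesh) {
  f <- mesh$faces
  cbind(from = c(f[, 1], f[, 2], f[, 3]), to = c(f[, 2], f[, 3], f[, 1]))
}

edge_keys <- function(e) {
  lo <- pmin(e[, 1], e[, 2])
  hi <- pmax(e[, 1], e[, 2])
  paste(lo, hi)
}

#' Boundary edges of a mesh
#'
#' Edges incident to exactly one face, in the winding direction of that face.
#' @param mesh a `triangle_mesh`.
#' @return integer matrix with columns `from`, `to` (possibly 0 rows).
#' @export
boundary_edges <- function(mesh) {
  he <- half_edges(mesh)
  k <- edge_keys(he)
  tab <- table(k)
  he[k %in% names(tab)[tab == 1L], , drop = FALSE]
}

#' Is the mesh watertight?
#'
#' A mesh is watertight (2-manifold closed) when every undirected edge is
#' shared by exactly two faces traversed in opposite directions.
#' @param mesh a `triangle_mesh`.
#' @export
is_watertight <- function(mesh) {
  if (n_faces(mesh) == 0) return(FALSE)
  he <- half_edges(mesh)
  k <- edge_keys(he)
  counts <- table(k)
  if (any(counts != 2L)) return(FALSE)
  # opposite traversal: each directed edge must appear exactly once
  dk <- paste(he[, 1], he[, 2])
  !anyDuplicated(dk)
}

#' Boundary loops
#'
#' Splits the boundary edges into closed vertex cycles.
#' @param mesh a `triangle_mesh`.
#' @return list of integer vectors (ordered vertex indices, one per loop).
#' @export
boundary_loops <- function(mesh) {
  be <- boundary_edges(mesh)
  if (nrow(be) == 0) return(list())
  nxt <- stats::setNames(be[, 2], as.character(be[, 1]))
  if (anyDuplicated(names(nxt)) || anyDuplicated(unname(nxt)))
    tf_stop("non-manifold boundary: a vertex joins more than two boundary edges",
            "tf_closure_error")
  remaining <- rep(TRUE, nrow(be))
  names(remaining) <- as.character(be[, 1])
  loops <- list()
  visited <- character(0)
  for (start in as.character(be[, 1])) {
    if (start %in% visited) next
    loop <- integer(0)
    cur <- start
    repeat {
      loop <- c(loop, as.integer(cur))
      visited <- c(visited, cur)
      nx <- unname(nxt[cur])
      if (is.na(nx))
        tf_stop("open boundary chain: boundary does not close", "tf_closure_error")
      cur <- as.character(nx)
      if (cur == start) break
    }
    loops[[length(loops) + 1]] <- loop
  }
  loops
}

#' Signed volume of a closed mesh (mm^3)
#'
#' Divergence-theorem volume: the sum of signed tetrahedra spanned by each
#' face and the origin. Positive for consistent outward orientation, and
#' invariant under rigid transforms.
#'
#' @param mesh a `triangle_mesh`.
#' @param check_watertight verify the strict edge-pairing closure test
#'   first. Set `FALSE` for meshes that are geometrically closed but carry
#'   T-junction vertices (e.g. Boolean intersection output), for which the
#'   divergence sum is still exact.
#' @export
signed_volume <- function(mesh, check_watertight = TRUE) {
  if (n_faces(mesh) == 0) return(0)
  if (check_watertight && !is_watertight(mesh)) {
    be <- boundary_edges(mesh)
    tf_stop(sprintf(
      "mesh is not watertight: %d open boundary edge(s), e.g. %s",
      nrow(be),
      paste(utils::head(apply(be, 1, paste, collapse = "-"), 5), collapse = ", ")),
      "tf_not_watertight")
  }
  fc <- face_corners(mesh)
  sum(rowSums(fc$a * row_cross(fc$b, fc$c))) / 6
}

#' Center of volume of a closed mesh
#'
#' Volume centroid via signed-tetrahedron first moments; translating the
#' mesh by minus this point centres it at the origin.
#' @inheritParams signed_volume
#' @return length-3 numeric (mm).
#' @export
center_of_volume <- function(mesh, check_watertight = TRUE) {
  v <- signed_volume(mesh, check_watertight = check_watertight)
  if (v <= 0) tf_stop("center_of_volume needs positive enclosed volume", "tf_domain_error")
  fc <- face_corners(mesh)
  w <- rowSums(fc$a * row_cross(fc$b, fc$c)) / 6
  ctr <- (fc$a + fc$b + fc$c) / 4   # tetra centroid with origin vertex
  colSums(ctr * w) / sum(w)
}

#' Merge coincident vertices
#'
#' Welds vertices that agree within `tol` (snap-to-grid) and drops faces that
#' become degenerate (repeated indices or zero area).
#' @param mesh a `triangle_mesh`.
#' @param tol weld tolerance in mm.
#' @return a `triangle_mesh` with attribute `diagnostics`.
#' @export
mesh_weld <- function(mesh, tol = 1e-6) {
  v <- mesh$vertices
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  first <- !duplicated(key)
  map <- match(key, key[first])
  newv <- v[first, , drop = FALSE]
  f <- matrix(map[mesh$faces], ncol = 3)
  dup_count <- nrow(v) - nrow(newv)
  degenerate <- (f[, 1] == f[, 2]) | (f[, 2] == f[, 3]) | (f[, 1] == f[, 3])
  f <- f[!degenerate, , drop = FALSE]
  out <- triangle_mesh(newv, f)
  ar <- face_areas(out)
  zero <- ar < (tol^2)
  if (any(zero)) out$faces <- out$faces[!zero, , drop = FALSE]
  attr(out, "diagnostics") <- list(
    duplicates_merged = dup_count,
    degenerate_faces_removed = sum(degenerate) + sum(zero))
  out
}

#' Make face windings consistent
#'
#' Propagates orientation across shared edges (breadth-first over the face
#' adjacency graph) and, if the mesh is closed, flips the whole mesh so the
#' enclosed volume is positive.
#' @param mesh a `triangle_mesh`.
#' @export
orient_consistently <- function(mesh) {
  nf <- n_faces(mesh)
  if (nf < 2) return(mesh)
  f <- mesh$faces
  he <- half_edges(mesh)
  face_of <- rep(seq_len(nf), 3)
  k <- edge_keys(he)
  # adjacency: faces sharing an undirected edge
  ord <- order(k)
  ks <- k[ord]
  fs <- face_of[ord]
  dirs <- (he[, 1] < he[, 2])[ord]  # direction flag of each half-edge
  same <- ks[-1] == ks[-length(ks)]
  adj_a <- fs[c(same, FALSE)]
  adj_b <- fs[c(FALSE, same)]
  agree <- dirs[c(same, FALSE)] != dirs[c(FALSE, same)]  # opposite traversal
  nbr <- vector("list", nf)
  for (i in seq_along(adj_a)) {
    nbr[[adj_a[i]]] <- rbind(nbr[[adj_a[i]]], c(adj_b[i], agree[i]))
    nbr[[adj_b[i]]] <- rbind(nbr[[adj_b[i]]], c(adj_a[i], agree[i]))
  }
  flip <- rep(NA, nf)
  for (seed_face in seq_len(nf)) {
    if (!is.na(flip[seed_face])) next
    flip[seed_face] <- FALSE
    queue <- seed_face
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      nb <- nbr[[cur]]
      if (is.null(nb)) next
      for (r in seq_len(nrow(nb))) {
        j <- nb[r, 1]; ok <- as.logical(nb[r, 2])
        want <- if (ok) flip[cur] else !flip[cur]
        if (is.na(flip[j])) {
          flip[j] <- want
          queue <- c(queue, j)
        }
      }
    }
  }
  f[flip, ] <- f[flip, c(1, 3, 2)]
  out <- triangle_mesh(mesh$vertices, f)
  if (is_watertight(out) && signed_volume(out) < 0)
    out$faces <- out$faces[, c(1, 3, 2)]
  attr(out, "diagnostics") <- attr(mesh, "diagnostics")
  out
}

#' Combine two meshes into one vertex/face set
#' @param a,b `triangle_mesh` objects.
#' @export
mesh_union_raw <- function(a, b) {
  triangle_mesh(rbind(a$vertices, b$vertices),
                rbind(a$faces, b$faces + nrow(a$vertices)))
}
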
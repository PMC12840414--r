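#' Read a surface mesh from an STL file
#'
#' Reads binary or ASCII stereolithography files (dialect auto-detected),
#' welds coincident vertices within `tol`, removes degenerate facets and
#' makes face windings consistent. STL carries no units; coordinates are
#' interpreted as mm by the package contract.
#'
#' @param path file path.
#' @param tol vertex weld tolerance in mm.
#' @return a `triangle_mesh`; attribute `diagnostics` records the number of
#'   duplicate vertices merged and degenerate facets removed.
#' @export
read_mesh <- function(path, tol = 1e-6) {
  if (!file.exists(path)) tf_stop(paste("file not found:", path), "tf_format_error")
  raw_tris <- if (is_binary_stl(path)) {
    read_stl_binary(path)
  } else if (looks_ascii_stl(path)) {
    read_stl_ascii(path)
  } else {
    tf_stop("not a valid STL file (truncated binary or unknown format)",
            "tf_format_error")
  }
  if (nrow(raw_tris) == 0) tf_stop("STL file contains no facets", "tf_empty_input")
  nf <- nrow(raw_tris) / 3
  mesh <- triangle_mesh(raw_tris, matrix(seq_len(3 * nf), ncol = 3, byrow = TRUE))
  mesh <- mesh_weld(mesh, tol = tol)
  if (n_faces(mesh) == 0) tf_stop("STL file contains only degenerate facets", "tf_empty_input")
  orient_consistently(mesh)
}

# binary iff the 84-byte header's facet count matches the file size
is_binary_stl <- function(path) {
  size <- file.info(path)$size
  if (is.na(size) || size < 84) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  n <- readBin(con, "integer", 1, size = 4)
  !is.na(n) && n >= 0 && size == 84 + 50 * n
}

looks_ascii_stl <- function(path) {
  head <- tryCatch(suppressWarnings(readLines(path, n = 1, warn = FALSE)),
                   error = function(e) "")
  length(head) == 1 && grepl("^\\s*solid", head)
}

read_stl_binary <- function(path) {
  size <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  n <- readBin(con, "integer", 1, size = 4)
  if (n == 0) return(matrix(numeric(0), ncol = 3))
  body <- readBin(con, "raw", 50 * n)
  if (length(body) < 50 * n) tf_stop("truncated binary STL", "tf_format_error")
  # keep the 48 float bytes of each 50-byte record
  rec <- matrix(body, nrow = 50)
  floats <- readBin(as.vector(rec[1:48, , drop = FALSE]), "numeric",
                    n = 12 * n, size = 4)
  per <- matrix(floats, nrow = 12)          # normal(3) + 3 vertices
  verts <- t(per[4:12, , drop = FALSE])     # n x 9
  matrix(t(matrix(t(verts), nrow = 3)), ncol = 3, byrow = FALSE)
}

read_stl_ascii <- function(path) {
  txt <- tryCatch(readLines(path, warn = FALSE), error = function(e)
    tf_stop("unreadable STL file", "tf_format_error"))
  vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
  if (length(vl) %% 3 != 0)
    tf_stop("malformed ASCII STL: vertex count not a multiple of 3", "tf_format_error")
  if (length(vl) == 0) return(matrix(numeric(0), ncol = 3))
  nums <- vapply(strsplit(trimws(vl), "\\s+"), function(p) as.numeric(p[2:4]),
                 numeric(3))
  if (any(!is.finite(nums))) tf_stop("non-numeric vertex in ASCII STL", "tf_format_error")
  t(nums)
}

#' Write a mesh to an STL file
#'
#' @param mesh a `triangle_mesh`.
#' @param path output file path.
#' @param format `"binary"` (default) or `"ascii"`. Binary STL stores
#'   32-bit floats; round-trip precision is about 1e-7 relative.
#' @export
write_mesh <- function(mesh, path, format = c("binary", "ascii")) {
  format <- match.arg(format)
  fc <- face_corners(mesh)
  nrm <- row_cross(fc$b - fc$a, fc$c - fc$a)
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len
  if (format == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(n_faces(mesh)), con, size = 4)
    if (n_faces(mesh) > 0) {
      dat <- cbind(nrm, fc$a, fc$b, fc$c)           # n x 12
      fl <- writeBin(as.numeric(t(dat)), raw(), size = 4)
      rec <- matrix(fl, nrow = 48)
      rec <- rbind(rec, matrix(as.raw(0), 2, ncol(rec)))
      writeBin(as.vector(rec), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid mesh", con)
    if (n_faces(mesh) > 0) {
      lines <- sprintf(
        "facet normal %.9e %.9e %.9e\n outer loop\n  vertex %.9e %.9e %.9e\n  vertex %.9e %.9e %.9e\n  vertex %.9e %.9e %.9e\n endloop\nendfacet",
        nrm[, 1], nrm[, 2], nrm[, 3],
        fc$a[, 1], fc$a[, 2], fc$a[, 3],
        fc$b[, 1], fc$b[, 2], fc$b[, 3],
        fc$c[, 1], fc$c[, 2], fc$c[, 3])
      writeLines(lines, con)
    }
    writeLines("endsolid mesh", con)
  }
  invisible(path)
}

#' Write a mesh in OFF format (debugging aid)
#' @param mesh a `triangle_mesh`.
#' @param path output file path.
#' @export
write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", n_vertices(mesh), n_faces(mesh)), con)
  writeLines(sprintf("%.9e %.9e %.9e", mesh$vertices[, 1], mesh$vertices[, 2],
                     mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                     mesh$faces[, 3] - 1L), con)
  invisible(path)
}
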
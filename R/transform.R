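#' Rigid transform
#'
#' A proper rigid motion: `x -> R x + t` with `R` orthonormal and
#' `det(R) = +1` (tolerance 1e-8).
#'
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 numeric (mm).
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  if (length(translation) != 3 || any(!is.finite(rotation)) || any(!is.finite(translation)))
    tf_stop("invalid rigid transform components", "tf_domain_error")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      abs(det(rotation) - 1) > 1e-8)
    tf_stop("rotation must be orthonormal with determinant +1", "tf_domain_error")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\nrotation:\n")
  print(round(x$rotation, 6))
  cat("translation:", paste(round(x$translation, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Rotation about an axis through the origin
#' @param axis length-3 direction (need not be unit).
#' @param angle radians.
#' @export
rotation_about_axis <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s <- sin(angle)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + s * K + (1 - c_) * (K %*% K)
}

#' Compose transforms: apply `first`, then `second`
#' @param second,first `rigid_transform` objects.
#' @export
compose_transforms <- function(second, first) {
  rigid_transform(second$rotation %*% first$rotation,
                  as.numeric(second$rotation %*% first$translation) + second$translation)
}

#' Inverse of a rigid transform
#' @param tf a `rigid_transform`.
#' @export
invert_transform <- function(tf) {
  rigid_transform(t(tf$rotation), as.numeric(-t(tf$rotation) %*% tf$translation))
}

#' Apply a rigid transform
#'
#' Volume and all pairwise distances are preserved (an isometry).
#' @param x a `triangle_mesh` or an `n x 3` point matrix / length-3 point.
#' @param tf a `rigid_transform`.
#' @export
apply_transform <- function(x, tf) {
  if (!inherits(tf, "rigid_transform")) tf <- do.call(rigid_transform, tf)
  UseMethod("apply_transform")
}

#' @export
apply_transform.triangle_mesh <- function(x, tf) {
  out <- x
  out$vertices <- transform_points(x$vertices, tf)
  out
}

#' @export
apply_transform.default <- function(x, tf) transform_points(x, tf)

transform_points <- function(p, tf) {
  single <- is.null(dim(p))
  p <- matrix(as.numeric(p), ncol = 3)
  out <- p %*% t(tf$rotation)
  out <- sweep(out, 2, tf$translation, "+")
  if (single) as.numeric(out) else `colnames<-`(out, c("x", "y", "z"))
}

#' Uniform scaling about a centre
#'
#' Scales all vertices by `s` about `center`; enclosed volume is multiplied
#' by `s^3`.
#' @param mesh a `triangle_mesh`.
#' @param s positive scale factor (the tooth-to-face protocol default is
#'   15.56, the mean bizygomatic-to-tooth width ratio).
#' @param center length-3 fixed point of the scaling.
#' @export
uniform_scale <- function(mesh, s, center = c(0, 0, 0)) {
  if (!is.numeric(s) || length(s) != 1 || !is.finite(s) || s <= 0)
    tf_stop("scale factor must be a positive number", "tf_domain_error")
  out <- mesh
  out$vertices <- sweep(sweep(mesh$vertices, 2, center, "-") * s, 2, center, "+")
  out
}

#' Scale a set of labelled points
#' @param points n x 3 matrix or length-3 point.
#' @param s positive scalar.
#' @param center fixed point.
#' @keywords internal
scale_points <- function(points, s, center = c(0, 0, 0)) {
  single <- is.null(dim(points))
  p <- matrix(as.numeric(points), ncol = 3)
  out <- sweep(sweep(p, 2, center, "-") * s, 2, center, "+")
  if (single) as.numeric(out) else out
}
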
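TOOTH_LANDMARK_NAMES <- c("incisal_midpoint", "mesial_edge_midpoint",
                          "distal_edge_midpoint", "cervical_midpoint")
FACE_LANDMARK_REQUIRED <- c("glabella", "pogonion", "menton",
                            "labiale_superius", "zygion_left", "zygion_right",
                            "alare_left", "alare_right")
FACE_LANDMARK_OPTIONAL <- c("nasion", "exocanthion_left", "exocanthion_right",
                            "endocanthion_left", "endocanthion_right",
                            "cheilion_left", "cheilion_right")

check_point <- function(p, name) {
  if (!is.numeric(p) || length(p) != 3 || any(!is.finite(p)))
    tf_stop(paste("landmark", name, "must be a finite 3-D point"),
            "tf_domain_error")
  as.numeric(p)
}

#' Tooth landmarks
#'
#' The four anatomical points on the buccal surface of the maxillary central
#' incisor that drive the tooth alignment: the incisal edge midpoint, the
#' mesial and distal proximal-edge midpoints, and the cervical margin
#' midpoint. Coordinates in mm, in the frame of the tooth scan.
#'
#' @param incisal_midpoint,mesial_edge_midpoint,distal_edge_midpoint,cervical_midpoint length-3 numeric points.
#' @export
tooth_landmarks <- function(incisal_midpoint, mesial_edge_midpoint,
                            distal_edge_midpoint, cervical_midpoint) {
  lm <- list(incisal_midpoint = check_point(incisal_midpoint, "incisal_midpoint"),
             mesial_edge_midpoint = check_point(mesial_edge_midpoint, "mesial_edge_midpoint"),
             distal_edge_midpoint = check_point(distal_edge_midpoint, "distal_edge_midpoint"),
             cervical_midpoint = check_point(cervical_midpoint, "cervical_midpoint"))
  if (sqrt(sum((lm$mesial_edge_midpoint - lm$distal_edge_midpoint)^2)) < 1e-9)
    tf_stop("mesial and distal edge midpoints coincide", "tf_degenerate_configuration")
  if (sqrt(sum((lm$incisal_midpoint - lm$cervical_midpoint)^2)) < 1e-9)
    tf_stop("incisal and cervical midpoints coincide", "tf_degenerate_configuration")
  structure(lm, class = "tooth_landmarks")
}

#' Facial landmarks
#'
#' The anthropometric points of the facial scan used in alignment and
#' tangency placement: glabella, pogonion, menton and labiale superius on
#' the midline, plus the paired zygion (zygomatic prominence) and alare
#' (nasal wing) points. Optional extra points (nasion, exocanthion,
#' endocanthion, cheilion pairs) are carried through but unused.
#'
#' @param glabella,pogonion,menton,labiale_superius,zygion_left,zygion_right,alare_left,alare_right length-3 points (mm).
#' @param ... optional named landmarks from the recognised extra set.
#' @export
face_landmarks <- function(glabella, pogonion, menton, labiale_superius,
                           zygion_left, zygion_right, alare_left, alare_right,
                           ...) {
  lm <- list(glabella = check_point(glabella, "glabella"),
             pogonion = check_point(pogonion, "pogonion"),
             menton = check_point(menton, "menton"),
             labiale_superius = check_point(labiale_superius, "labiale_superius"),
             zygion_left = check_point(zygion_left, "zygion_left"),
             zygion_right = check_point(zygion_right, "zygion_right"),
             alare_left = check_point(alare_left, "alare_left"),
             alare_right = check_point(alare_right, "alare_right"))
  extra <- list(...)
  if (length(extra)) {
    bad <- setdiff(names(extra), FACE_LANDMARK_OPTIONAL)
    if (length(bad))
      tf_stop(paste("unknown landmark name(s):", paste(bad, collapse = ", ")),
              "tf_missing_landmark")
    for (nm in names(extra)) lm[[nm]] <- check_point(extra[[nm]], nm)
  }
  for (pair in list(c("zygion_left", "zygion_right"),
                    c("alare_left", "alare_right"))) {
    if (sqrt(sum((lm[[pair[1]]] - lm[[pair[2]]])^2)) < 1e-9)
      tf_stop(paste(pair[1], "and", pair[2], "coincide"),
              "tf_degenerate_configuration")
  }
  if (sqrt(sum((lm$glabella - lm$pogonion)^2)) < 1e-9)
    tf_stop("glabella and pogonion coincide (no vertical facial line)",
            "tf_degenerate_configuration")
  structure(lm, class = "face_landmarks")
}

#' Transform a landmark set
#' @param lm a `tooth_landmarks` or `face_landmarks` object.
#' @param tf a `rigid_transform`.
#' @export
transform_landmarks <- function(lm, tf) {
  out <- lapply(unclass(lm), transform_points, tf = tf)
  class(out) <- class(lm)
  out
}

#' Scale a landmark set about a centre
#' @param lm landmark set.
#' @param s positive scalar.
#' @param center fixed point.
#' @export
scale_landmarks <- function(lm, s, center = c(0, 0, 0)) {
  out <- lapply(unclass(lm), scale_points, s = s, center = center)
  class(out) <- class(lm)
  out
}

#' Read landmarks from a JSON sidecar
#'
#' The sidecar maps landmark names to `[x, y, z]` mm triplets; names must
#' match the type definitions exactly and unknown names are rejected.
#'
#' @param path JSON file path.
#' @param type `"tooth"` or `"face"`.
#' @export
read_landmarks <- function(path, type = c("tooth", "face")) {
  type <- match.arg(type)
  if (!file.exists(path))
    tf_stop(paste("landmark file not found:", path), "tf_missing_landmark")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (type == "tooth") {
    bad <- setdiff(names(raw), TOOTH_LANDMARK_NAMES)
    if (length(bad))
      tf_stop(paste("unknown tooth landmark(s):", paste(bad, collapse = ", ")),
              "tf_missing_landmark")
    missing <- setdiff(TOOTH_LANDMARK_NAMES, names(raw))
    if (length(missing))
      tf_stop(paste("missing tooth landmark(s):", paste(missing, collapse = ", ")),
              "tf_missing_landmark")
    do.call(tooth_landmarks, raw[TOOTH_LANDMARK_NAMES])
  } else {
    bad <- setdiff(names(raw), c(FACE_LANDMARK_REQUIRED, FACE_LANDMARK_OPTIONAL))
    if (length(bad))
      tf_stop(paste("unknown face landmark(s):", paste(bad, collapse = ", ")),
              "tf_missing_landmark")
    missing <- setdiff(FACE_LANDMARK_REQUIRED, names(raw))
    if (length(missing))
      tf_stop(paste("missing face landmark(s):", paste(missing, collapse = ", ")),
              "tf_missing_landmark")
    do.call(face_landmarks, raw)
  }
}

#' Write landmarks to a JSON sidecar
#' @param lm landmark set.
#' @param path output path.
#' @export
write_landmarks <- function(lm, path) {
  jsonlite::write_json(lapply(unclass(lm), as.numeric), path,
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}
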
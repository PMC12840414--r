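#' Superimposition outcome metrics
#'
#' Houses the two outcome formulas of the volumetric protocol:
#' `RTV = V_total - V_superimposed` (remaining tooth volume) and
#' `%SI = V_superimposed / V_total * 100` (superimposition percentage).
#' The identity `V_superimposed + RTV = V_total` holds exactly by
#' construction.
#'
#' @param v_total total extruded tooth solid volume (mm^3), > 0.
#' @param v_superimposed overlap volume with the facial solid (mm^3),
#'   in `[0, v_total]`.
#' @param residuals optional named numeric (placement residuals, mm).
#' @param config optional configuration echo (list).
#' @return object of class `superimposition_result` with fields `V_total`,
#'   `V_superimposed`, `RTV`, `pct_SI`.
#' @export
compute_metrics <- function(v_total, v_superimposed, residuals = NULL,
                            config = NULL) {
  if (!is.numeric(v_total) || length(v_total) != 1 || !is.finite(v_total) ||
      v_total <= 0)
    tf_stop("V_total must be a positive number", "tf_domain_error")
  if (!is.numeric(v_superimposed) || length(v_superimposed) != 1 ||
      !is.finite(v_superimposed) || v_superimposed < 0)
    tf_stop("V_superimposed must be non-negative", "tf_domain_error")
  if (v_superimposed > v_total)
    tf_stop("V_superimposed exceeds V_total", "tf_inconsistency")
  structure(list(
    V_total = v_total,
    V_superimposed = v_superimposed,
    RTV = v_total - v_superimposed,
    pct_SI = v_superimposed / v_total * 100,
    residuals = residuals,
    config = config), class = "superimposition_result")
}

#' @export
print.superimposition_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<superimposition_result>\n",
    "  V_total        %14.2f mm^3\n",
    "  V_superimposed %14.2f mm^3\n",
    "  RTV            %14.2f mm^3\n",
    "  %%SI            %14.2f %%\n"),
    x$V_total, x$V_superimposed, x$RTV, x$pct_SI))
  if (!is.null(x$residuals))
    cat("  residuals:", paste(sprintf("%s=%.3g", names(x$residuals),
                                      x$residuals), collapse = ", "), "\n")
  invisible(x)
}

#' Pipeline configuration
#'
#' Preset parameters of the superimposition protocol. The scale factor
#' (15.56, the mean bizygomatic-to-tooth width ratio) and the extrusion
#' height (6 mm) are the study presets; both are overridable.
#'
#' @param scale uniform magnification applied to the extruded tooth.
#' @param extrusion extrusion height in mm (applied before scaling).
#' @param mode transverse tangency pair, `"zygion"` or `"alare"`.
#' @param smoothing_iters boundary Laplacian iterations for the patch.
#' @param cap_depth facial-solid cap depth in mm, or `NULL` for the rule
#'   `2 x` the scaled tooth solid's anteroposterior extent (any value
#'   beyond the tooth's posterior extent gives identical metrics).
#' @param alpha significance threshold used by the statistics layer.
#' @param z_offset extra anteroposterior tooth displacement (mm).
#' @export
pipeline_config <- function(scale = 15.56, extrusion = 6,
                            mode = c("zygion", "alare"), smoothing_iters = 5,
                            cap_depth = NULL, alpha = 0.05, z_offset = 0) {
  mode <- match.arg(mode)
  if (scale <= 0 || extrusion <= 0)
    tf_stop("scale and extrusion must be positive", "tf_domain_error")
  if (alpha <= 0 || alpha >= 1)
    tf_stop("alpha must be in (0, 1)", "tf_domain_error")
  structure(list(scale = scale, extrusion = extrusion, mode = mode,
                 smoothing_iters = smoothing_iters, cap_depth = cap_depth,
                 alpha = alpha, z_offset = z_offset),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    cls <- setdiff(class(e), c("error", "condition"))
    stop(structure(
      class = c(cls, "tf_stage_error", "error", "condition"),
      list(message = sprintf("[stage %s] %s", name, conditionMessage(e)),
           call = NULL)))
  })
}

#' Run the full tooth-face superimposition protocol
#'
#' Orchestrates the volumetric workflow for one subject: patch extraction
#' and boundary smoothing, extrusion to a solid (6 mm preset), uniform
#' scaling (15.56 preset), landmark alignment of tooth and face, tangency
#' placement, closure of the facial shell, Boolean intersection, and the
#' RTV / %SI outcome metrics. Deterministic: identical inputs give
#' identical results.
#'
#' @param tooth_scan `triangle_mesh` of the intraoral scan (or the patch
#'   itself).
#' @param face_scan `triangle_mesh` facial shell.
#' @param tooth_lm `tooth_landmarks` in the tooth scan frame.
#' @param face_lm `face_landmarks` in the face scan frame.
#' @param selection face indices of the buccal patch; `NULL` selects every
#'   face of `tooth_scan`.
#' @param config a `pipeline_config`.
#' @return a `superimposition_result`.
#' @export
run_superimposition <- function(tooth_scan, face_scan, tooth_lm, face_lm,
                                selection = NULL, config = pipeline_config()) {
  if (is.null(selection)) selection <- seq_len(n_faces(tooth_scan))
  patch <- stage("extract_patch",
                 extract_patch(tooth_scan, selection, config$smoothing_iters))
  solid <- stage("extrude_to_solid", extrude_to_solid(patch, config$extrusion))
  ctr <- center_of_volume(solid)
  scaled <- stage("uniform_scale", uniform_scale(solid, config$scale, ctr))
  lm_scaled <- scale_landmarks(tooth_lm, config$scale, ctr)
  tooth_al <- stage("align_tooth", align_tooth(scaled, lm_scaled))
  face_al <- stage("align_face", align_face(face_scan, face_lm))
  placement <- stage("place_for_superimposition",
                     place_for_superimposition(face_al$mesh, face_al$landmarks,
                                               tooth_al$mesh, tooth_al$landmarks,
                                               mode = config$mode,
                                               z_offset = config$z_offset))
  tooth_placed <- apply_transform(tooth_al$mesh, placement)
  cap_depth <- config$cap_depth
  if (is.null(cap_depth)) {
    # rule: twice the scaled tooth depth, and always behind the tooth's
    # posterior extent
    zr <- range(tooth_placed$vertices[, 3])
    depth <- zr[2] - zr[1]
    cap_depth <- max(2 * depth, -zr[1] + 0.5 * depth)
  }
  face_solid <- stage("face_to_solid", face_to_solid(face_al$mesh, cap_depth))
  inter <- stage("boolean_intersection",
                 boolean_intersection(tooth_placed, face_solid))
  v_total <- signed_volume(tooth_placed)
  v_sup <- attr(inter, "volume")
  if (v_sup > v_total) {
    if (v_sup > v_total * (1 + 1e-6))
      tf_stop("intersection volume exceeds tooth volume", "tf_inconsistency")
    v_sup <- v_total
  }
  compute_metrics(v_total, v_sup,
                  residuals = c(attr(placement, "residuals"),
                                tooth_al$residuals, face_al$residuals),
                  config = list(scale = config$scale,
                                extrusion = config$extrusion,
                                mode = config$mode,
                                cap_depth = cap_depth,
                                z_offset = config$z_offset))
}
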
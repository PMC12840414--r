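random_rigid <- function() {
  ax <- stats::rnorm(3)
  ang <- stats::runif(1, 0, 2 * pi)
  rigid_transform(rotation_about_axis(ax, ang), stats::runif(3, -30, 30))
}

#' Write a complete synthetic subject fixture
#'
#' Generates one subject's tooth patch and facial shell at congruence
#' `kappa`, applies independent seeded rigid motions to both scans (so the
#' pipeline's alignment steps are exercised), and writes the STL meshes and
#' JSON landmark sidecars plus a ground-truth record with the expected %SI
#' band implied by the construction: `(99, 100]` for `kappa = 1` without
#' noise, `[0, 0]` for a disjoint placement, and a loose `[80, 100]`
#' otherwise. Deterministic under `seed`: the same seed reproduces the
#' files byte for byte.
#'
#' @param dir output directory (created if needed).
#' @param kappa congruence in `[0, 1]`.
#' @param tooth_params,face_params shape parameter objects.
#' @param noise_sd facial surface noise SD, mm.
#' @param disjoint place the tooth fully anterior of the face
#'   (`z_offset = 400` mm in the returned config), giving %SI = 0.
#' @param seed integer seed.
#' @return list with file `paths`, the `expected_band` for %SI, and the
#'   `config` (`pipeline_config`) to run them with.
#' @export
gen_subject_meshes <- function(dir, kappa = 1,
                               tooth_params = tooth_shape_params(),
                               face_params = face_shape_params(),
                               noise_sd = 0, disjoint = FALSE, seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tooth <- gen_tooth(tooth_params, seed = seed)
  face <- gen_face(face_params, tooth, kappa, noise_sd = noise_sd,
                   seed = seed + 1L)
  tfs <- withr::with_seed(seed + 2L, list(random_rigid(), random_rigid()))
  tooth_mesh <- apply_transform(tooth$patch, tfs[[1]])
  tooth_lm <- transform_landmarks(tooth$landmarks, tfs[[1]])
  face_mesh <- apply_transform(face$shell, tfs[[2]])
  face_lm <- transform_landmarks(face$landmarks, tfs[[2]])
  paths <- list(
    tooth_stl = file.path(dir, "tooth.stl"),
    face_stl = file.path(dir, "face.stl"),
    tooth_landmarks = file.path(dir, "tooth_landmarks.json"),
    face_landmarks = file.path(dir, "face_landmarks.json"),
    truth = file.path(dir, "truth.json"))
  write_mesh(tooth_mesh, paths$tooth_stl, format = "binary")
  write_mesh(face_mesh, paths$face_stl, format = "binary")
  write_landmarks(tooth_lm, paths$tooth_landmarks)
  write_landmarks(face_lm, paths$face_landmarks)
  band <- if (disjoint) c(0, 0)
          else if (kappa == 1 && noise_sd == 0) c(99, 100)
          else c(80, 100)
  config <- pipeline_config(
    scale = face_params$ratio, extrusion = face_params$extrusion,
    smoothing_iters = face_params$smoothing_iters,
    z_offset = if (disjoint) 400 else 0)
  jsonlite::write_json(
    list(kappa = kappa, noise_sd = noise_sd, disjoint = disjoint,
         seed = seed, expected_band = band),
    paths$truth, auto_unbox = TRUE, digits = NA)
  list(paths = paths, expected_band = band, config = config)
}

#' Run the superimposition protocol on files
#'
#' Reads the STL meshes and JSON landmark sidecars, runs
#' [run_superimposition()] and (optionally) writes the result record as
#' JSON.
#'
#' @param tooth_stl,face_stl STL file paths.
#' @param tooth_landmarks,face_landmarks JSON sidecar paths.
#' @param selection optional file with one 1-based face index per line, or
#'   an integer vector; `NULL` selects all faces.
#' @param config a `pipeline_config`.
#' @param out_json optional output path for the result record.
#' @return the `superimposition_result`.
#' @export
superimpose_files <- function(tooth_stl, face_stl, tooth_landmarks,
                              face_landmarks, selection = NULL,
                              config = pipeline_config(), out_json = NULL) {
  tooth <- read_mesh(tooth_stl)
  face <- read_mesh(face_stl)
  t_lm <- read_landmarks(tooth_landmarks, "tooth")
  f_lm <- read_landmarks(face_landmarks, "face")
  if (is.character(selection) && length(selection) == 1)
    selection <- as.integer(readLines(selection))
  res <- run_superimposition(tooth, face, t_lm, f_lm, selection, config)
  if (!is.null(out_json)) {
    jsonlite::write_json(
      list(V_total = res$V_total, V_superimposed = res$V_superimposed,
           RTV = res$RTV, pct_SI = res$pct_SI,
           residuals = as.list(res$residuals), config = res$config),
      out_json, auto_unbox = TRUE, digits = NA)
  }
  res
}

#' Run the cohort statistics battery on a CSV and write report files
#'
#' @param cohort_csv input cohort CSV.
#' @param out_dir output directory for `report.json` and the descriptive
#'   table CSV.
#' @param alpha significance level.
#' @return the report (invisibly).
#' @export
cohort_report_files <- function(cohort_csv, out_dir, alpha = 0.05) {
  cohort <- read_cohort(cohort_csv)
  rep <- analysis_report(cohort, alpha = alpha)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(rep$descriptives, file.path(out_dir, "descriptives.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report_to_json(rep), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(rep)
}

report_to_json <- function(x) {
  if (inherits(x, "stat_result")) return(unclass(x))
  if (inherits(x, "tbl_df") || is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(x, report_to_json))
  x
}

#' Simulate cohort and mesh fixtures to disk
#'
#' Writes a cohort CSV with its ground-truth JSON and, optionally, one
#' subject's mesh fixture set. Deterministic under `seed`.
#'
#' @param out_dir output directory.
#' @param config a `cohort_sim_config`.
#' @param seed integer seed.
#' @param with_meshes also write one subject mesh fixture (kappa = 1).
#' @return list of written paths.
#' @export
simulate_fixtures <- function(out_dir, config = cohort_sim_config(), seed = 1,
                              with_meshes = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- gen_cohort_table(config, seed = seed)
  cohort_path <- file.path(out_dir, "cohort.csv")
  write_cohort(cohort, cohort_path)
  gt <- attr(cohort, "ground_truth")
  truth_path <- file.path(out_dir, "cohort_truth.json")
  jsonlite::write_json(
    list(n = gt$config$n, p_female = gt$config$p_female,
         pct_si_mean = gt$config$pct_si_mean,
         pct_si_sd = gt$config$pct_si_sd,
         rank_corr = as.list(gt$config$rank_corr),
         copula_r = as.list(gt$copula_r), seed = gt$seed),
    truth_path, auto_unbox = TRUE, digits = NA)
  out <- list(cohort = cohort_path, truth = truth_path)
  if (with_meshes)
    out$meshes <- gen_subject_meshes(file.path(out_dir, "subject01"),
                                     kappa = 1, seed = seed)$paths
  out
}
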
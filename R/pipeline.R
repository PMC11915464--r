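#' Default pipeline configuration
#'
#' All tunable parameters of the end-to-end cap build with their defaults,
#' serializable to/from JSON. Unknown keys are rejected on load.
#'
#' @return named list of parameters.
#' @export
default_config <- function() {
  list(
    system = "10-10",
    grommet_radius = 4,
    grommet_shape = "circle",
    keep_ratio = 0.05,
    wire_thickness = 2.5,
    face_width_fraction = 1 / 3,
    face_height_fraction = 0.55,
    neck_height_fraction = 1 / 3,
    ear_cutout = FALSE,
    margin_band_width = 10,
    cz_tol = 1e-6,
    max_circumradius = 2,
    threshold = NULL,
    voxel_pitch = NULL,         # default wire_thickness / 4
    target_circumference = NULL,
    seed = 1,
    verbosity = 1,
    input_mesh = NULL,
    input_volume = NULL,
    fiducials = NULL,           # path to JSON or named list of 5 points
    out_dir = "."
  )
}

#' Load and validate a pipeline configuration
#'
#' @param path JSON file with a (partial) configuration; missing keys take
#'   their defaults, unknown keys are an error.
#' @param overrides named list merged over the file values.
#' @return validated config list.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  user <- list()
  if (!is.null(path)) user <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  user <- utils::modifyList(user, overrides)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(cfg, user)
  if (cfg$keep_ratio <= 0 || cfg$keep_ratio > 1)
    stop("config: keep_ratio must be in (0, 1]")
  if (cfg$grommet_radius <= 0) stop("config: grommet_radius must be positive")
  cfg
}

read_fiducials_json <- function(x) {
  if (is.character(x) && length(x) == 1L) x <- jsonlite::fromJSON(x)
  names(x) <- tolower(names(x))
  need <- c("nz", "iz", "lpa", "rpa", "cz0")
  if (!all(need %in% names(x)))
    stop("fiducials need keys Nz, Iz, LPA, RPA, Cz0")
  fiducials(x$nz, x$iz, x$lpa, x$rpa, x$cz0)
}

write_landmarks_json <- function(landmarks, path) {
  pos <- lapply(seq_len(nrow(landmarks$positions)), function(i)
    unname(landmarks$positions[i, ]))
  names(pos) <- rownames(landmarks$positions)
  payload <- list(system = landmarks$system,
                  iterations = landmarks$iterations,
                  positions = pos)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

pipeline_log <- function(cfg, ...) {
  if (isTRUE(cfg$verbosity >= 1)) message(sprintf(...))
}

#' Run the full cap-design pipeline
#'
#' Stages: optional surface extraction from a volume, landmark computation,
#' cap building (coarsen, register, grommets, holes, margins, wireframe),
#' printable repair/validation, and metrology. Writes the head surface, the
#' landmark JSON, the raw and final cap STL, a defect report and a validation
#' report to `config$out_dir`, plus an echo of the resolved configuration.
#' Identical configuration and inputs give byte-identical landmark JSON and
#' defect reports (the pipeline is deterministic).
#'
#' @param config list from [default_config()] / [load_config()]; inputs are
#'   given either as file paths (`input_mesh` / `input_volume`, `fiducials`)
#'   or as in-memory objects (`mesh`, `volume`, `fiducials`).
#' @param mesh optional [trimesh] input overriding `config$input_mesh`.
#' @param volume optional [volume_image] overriding `config$input_volume`.
#' @param fid optional [fiducials] object.
#' @return invisible list with every intermediate artifact.
#' @export
run_pipeline <- function(config = default_config(), mesh = NULL, volume = NULL,
                         fid = NULL) {
  cfg <- utils::modifyList(default_config(), config)
  # validate before anything is written
  if (cfg$keep_ratio <= 0 || cfg$keep_ratio > 1)
    stop("config: keep_ratio must be in (0, 1]")
  if (cfg$grommet_radius <= 0) stop("config: grommet_radius must be positive")
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "inputs"
  res <- tryCatch({
    if (is.null(volume) && !is.null(cfg$input_volume))
      volume <- read_volume(cfg$input_volume)
    if (is.null(mesh) && !is.null(cfg$input_mesh))
      mesh <- read_mesh(cfg$input_mesh)
    if (is.null(fid) && !is.null(cfg$fiducials))
      fid <- read_fiducials_json(cfg$fiducials)
    if (is.null(fid)) stop("no fiducials provided")

    if (is.null(mesh)) {
      stage <- "extract-surface"
      if (is.null(volume)) stop("need either a mesh or a volume input")
      pipeline_log(cfg, "[extract-surface] %s voxels",
                   paste(dim(volume$array), collapse = "x"))
      mesh <- extract_head_surface(volume, extraction_params(
        threshold = cfg$threshold, max_circumradius = cfg$max_circumradius))
      write_mesh(mesh, file.path(out_dir, "head.stl"))
    }
    pipeline_log(cfg, "[head] %d vertices, %d faces",
                 nrow(mesh$vertices), nrow(mesh$faces))

    stage <- "landmarks"
    lmk <- compute_landmarks(mesh, fid, system = cfg$system,
                             cz_tol = cfg$cz_tol)
    write_landmarks_json(lmk, file.path(out_dir, "landmarks.json"))
    pipeline_log(cfg, "[landmarks] %d labels, Cz in %d iterations",
                 nrow(lmk$positions), lmk$iterations)

    stage <- "build-cap"
    if (!is.null(cfg$target_circumference)) {
      mesh <- scale_to_circumference(mesh, lmk, cfg$target_circumference)
      lmk <- compute_landmarks(mesh, transform_fiducials(
        fid, diag(3) * attr(mesh, "scale"),
        (1 - attr(mesh, "scale")) * as.numeric((fid$lpa + fid$rpa) / 2)),
        system = cfg$system, cz_tol = cfg$cz_tol)
    }
    body <- coarsen(mesh, cfg$keep_ratio)
    pipeline_log(cfg, "[coarsen] keep_ratio %.3g -> %d edges (Hausdorff %.2f mm)",
                 cfg$keep_ratio, nrow(mesh_edges(body)), attr(body, "hausdorff"))
    reg <- register_landmarks(lmk, body)
    if (isTRUE(cfg$verbosity >= 2))
      message(paste(sprintf("  snap %s: %.3f mm", names(reg$snap_dist),
                            reg$snap_dist), collapse = "\n"))
    gspec <- grommet_spec(shape = cfg$grommet_shape,
                          radius = cfg$grommet_radius,
                          cutter_depth = 8 * cfg$wire_thickness)
    cutters <- place_grommets(body, reg, gspec)
    holed <- cut_grommet_holes(body, cutters)
    pipeline_log(cfg, "[grommets] %d holes cut", length(cutters))
    cparams <- cap_params(keep_ratio = cfg$keep_ratio,
                          wire_thickness = cfg$wire_thickness,
                          face_width_fraction = cfg$face_width_fraction,
                          face_height_fraction = cfg$face_height_fraction,
                          neck_height_fraction = cfg$neck_height_fraction,
                          ear_cutout = cfg$ear_cutout,
                          margin_band_width = cfg$margin_band_width)
    cap <- cut_margins(holed, fid, cparams)
    cap <- thicken_margin(cap, cparams$margin_band_width)
    pipeline_log(cfg, "[margins] %d boundary loops, %d margin-tagged edges",
                 length(mesh_boundary_loops(cap)), sum(attr(cap, "margin_tags")))
    pitch <- cfg$voxel_pitch
    if (is.null(pitch)) pitch <- cfg$wire_thickness / 4
    solid <- wireframe(cap, cfg$wire_thickness, pitch = pitch)
    write_mesh(solid, file.path(out_dir, "cap.stl"))
    pipeline_log(cfg, "[wireframe] %d faces, volume %.0f mm^3",
                 nrow(solid$faces), mesh_volume(solid))

    stage <- "make-printable"
    report <- diagnose(solid)
    jsonlite::write_json(unclass(report), file.path(out_dir, "defects.json"),
                         digits = NA, auto_unbox = TRUE)
    if (!is_printable(report)) stop("final cap is not printable; see defects.json")

    stage <- "measure"
    validation <- validate_cap_landmarks(mesh, reg, cap,
                                         max_dist = 2 * cfg$grommet_radius)
    jsonlite::write_json(list(r_squared = validation$r_squared,
                              mean_error = validation$mean_error,
                              sd_error = validation$sd_error,
                              circumference = circumference(mesh, lmk),
                              pairs = validation$pairs),
                         file.path(out_dir, "validation.json"),
                         digits = NA, auto_unbox = TRUE)
    jsonlite::write_json(cfg[!vapply(cfg, is.null, TRUE)],
                         file.path(out_dir, "config.json"),
                         digits = NA, auto_unbox = TRUE)
    pipeline_log(cfg, "[measure] R^2 %.5f, error %.3f +/- %.3f mm",
                 validation$r_squared, validation$mean_error,
                 validation$sd_error)
    list(head = mesh, landmarks = lmk, registered = reg, body = body,
         cap = cap, solid = solid, report = report, validation = validation,
         config = cfg)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage [%s]: %s (artifacts in %s)",
                 stage, conditionMessage(e), out_dir), call. = FALSE)
  })
  invisible(res)
}
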
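#' Pipeline configuration
#'
#' Bundle of all stage parameters for [run_pipeline()]. Exactly one of
#' `input_volume` (+ `landmarks`) or `phantom` must be given.
#'
#' @param input_volume path to a TIFF/NIfTI volume, or a [voxel_volume].
#' @param landmarks path to a landmark JSON (see [read_landmarks()]) or a
#'   named list; required with `input_volume`.
#' @param phantom a [phantom_spec]: generate the input synthetically.
#' @param bone_threshold length-2 intensity window selecting bone.
#' @param inclusion_threshold length-2 intensity window selecting dense
#'   inclusions (cochleoliths); `NULL` disables inclusion analysis.
#' @param min_component_vox connected-component noise floor (voxels).
#' @param freq_params a [freq_map_params].
#' @param f_min_hz,f_max_hz octave-band range (default: full map range).
#' @param porosity_backend `"voxel"` or `"mesh_wrap"`.
#' @param closing_radius_vox pore-filling ball radius (voxel backend).
#' @param n_steps_per_turn angular sampling density.
#' @param export_stl write STL meshes of the original and filled plates.
#' @param seed RNG seed (phantom generation).
#' @param verbose log progress to stderr.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_volume = NULL, landmarks = NULL,
                            phantom = NULL,
                            bone_threshold = c(120, 220),
                            inclusion_threshold = c(230, Inf),
                            min_component_vox = 27L,
                            freq_params = freq_map_params(),
                            f_min_hz = NULL, f_max_hz = NULL,
                            porosity_backend = c("voxel", "mesh_wrap"),
                            closing_radius_vox = 3,
                            n_steps_per_turn = 90L,
                            export_stl = FALSE, seed = 1L, verbose = FALSE) {
  porosity_backend <- match.arg(porosity_backend)
  if (is.null(input_volume) == is.null(phantom))
    .stopf("config error: exactly one of `input_volume` or `phantom` must be set")
  if (!is.null(input_volume) && is.null(landmarks))
    .stopf("config error: `landmarks` are required with `input_volume`")
  if (!is.null(phantom) && !inherits(phantom, "phantom_spec"))
    .stopf("config error: `phantom` must be a phantom_spec")
  structure(list(input_volume = input_volume, landmarks = landmarks,
                 phantom = phantom, bone_threshold = bone_threshold,
                 inclusion_threshold = inclusion_threshold,
                 min_component_vox = min_component_vox,
                 freq_params = freq_params,
                 f_min_hz = f_min_hz, f_max_hz = f_max_hz,
                 porosity_backend = porosity_backend,
                 closing_radius_vox = closing_radius_vox,
                 n_steps_per_turn = n_steps_per_turn,
                 export_stl = export_stl, seed = as.integer(seed),
                 verbose = verbose),
            class = "pipeline_config")
}

.log <- function(cfg, fmt, ...) {
  if (isTRUE(cfg$verbose)) message(sprintf(fmt, ...))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full morphometry pipeline
#'
#' Phantom generation (or volume loading), bone segmentation, spiral
#' contouring, OSL width profiling, tonotopic octave-band statistics,
#' inclusion localisation and per-segment plate porosity, written as a
#' CSV/JSON (and optionally STL) report bundle.
#'
#' @param cfg a [pipeline_config].
#' @param out_dir output directory (created if missing).
#' @return invisibly, the summary list (also written as `summary.json`):
#'   elements `seed`, `width` (range and sample count), `bands`
#'   (per-band width stats), `porosity` (per segment and plate),
#'   `inclusion` (band overlap fractions, when present).
#' @export
run_pipeline <- function(cfg, out_dir) {
  if (!inherits(cfg, "pipeline_config")) .stopf("`cfg` must be a pipeline_config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(cfg$phantom)) {
    .log(cfg, "generating phantom (seed %d)", cfg$seed)
    spec <- cfg$phantom
    spec$seed <- cfg$seed
    ph <- .stage("phantom", generate_phantom(spec, cfg$freq_params))
    vol <- ph$volume
    lm <- ph$landmarks
  } else {
    .log(cfg, "loading %s", cfg$input_volume)
    vol <- .stage("io", if (inherits(cfg$input_volume, "voxel_volume"))
      cfg$input_volume else read_volume(cfg$input_volume))
    lm <- .stage("io", if (is.character(cfg$landmarks))
      read_landmarks(cfg$landmarks) else cfg$landmarks)
  }

  .log(cfg, "segmenting bone in [%g, %g]", cfg$bone_threshold[1], cfg$bone_threshold[2])
  bone <- .stage("segmentation", {
    m <- threshold_segment(vol, threshold_rule(cfg$bone_threshold[1],
                                               cfg$bone_threshold[2]))
    remove_small_components(m, cfg$min_component_vox)
  })

  incl <- NULL
  if (!is.null(cfg$inclusion_threshold)) {
    incl <- .stage("segmentation", {
      m <- threshold_segment(vol, threshold_rule(cfg$inclusion_threshold[1],
                                                 cfg$inclusion_threshold[2]))
      remove_small_components(m, max(8L, cfg$min_component_vox %/% 3L))
    })
    if (sum(incl$data) == 0) incl <- NULL
  }

  frame <- .stage("geometry",
    build_reference_frame(lm$center, lm$helicotrema, lm$basal))
  .log(cfg, "contouring spiral walls")
  contours <- .stage("geometry",
    extract_wall_contours(bone, frame, cfg$n_steps_per_turn))
  profile <- .stage("geometry", width_profile(contours))
  profile <- .stage("tonotopy", attach_position(profile, cfg$freq_params))
  partitions <- .stage("tonotopy",
    octave_partitions(cfg$freq_params, cfg$f_min_hz, cfg$f_max_hz))
  bands <- .stage("tonotopy", band_stats(profile, partitions))

  .log(cfg, "porosity analysis (%s backend)", cfg$porosity_backend)
  poro <- .stage("porosity",
    segment_porosity(bone, frame, backend = cfg$porosity_backend,
                     closing_radius_vox = cfg$closing_radius_vox,
                     n_steps_per_turn = cfg$n_steps_per_turn))

  incl_tab <- NULL
  if (!is.null(incl)) {
    centerline <- attr(profile, "midpoints_mm")
    incl_tab <- .stage("tonotopy",
      localize_inclusion(incl, centerline, partitions, cfg$freq_params))
  }

  write_report(data.frame(angle_deg = profile$angle_deg,
                          x_norm = profile$x_norm,
                          width_mm = profile$width_mm),
               file.path(out_dir, "width.csv"))
  write_report(bands, file.path(out_dir, "bands.csv"))
  write_report(poro, file.path(out_dir, "porosity.csv"))
  if (!is.null(incl_tab))
    write_report(incl_tab, file.path(out_dir, "inclusion.csv"))
  if (isTRUE(cfg$export_stl)) {
    .stage("porosity", {
      plates <- split_plates(bone, frame, cfg$n_steps_per_turn)
      for (pl in names(plates)) {
        write_mesh(mask_to_mesh(plates[[pl]]),
                   file.path(out_dir, sprintf("%s.stl", pl)))
        write_mesh(mask_to_mesh(fill_pores_voxel(plates[[pl]],
                                                 cfg$closing_radius_vox)),
                   file.path(out_dir, sprintf("%s_filled.stl", pl)))
      }
    })
  }

  summary <- list(
    seed = cfg$seed,
    width = list(n_samples = nrow(profile),
                 min_mm = min(profile$width_mm),
                 max_mm = max(profile$width_mm)),
    bands = bands,
    porosity = poro,
    inclusion = incl_tab)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(summary)
}
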
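#' Default pipeline configuration
#'
#' Parameters of the full quantitative 3D-reconstruction pipeline with
#' defaults mirroring the reference scene: 6 um nuclei sectioned at
#' t = 7 um, imaged at 0.9 um/pixel, 26 um boxels and a 130 um (5-boxel)
#' sample volume. The configuration round-trips through YAML
#' ([read_pipeline_config()] / [write_pipeline_config()]).
#'
#' @param ... named overrides of any default entry.
#' @return a named list (class `pipeline_config`).
#' @export
default_pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    # synthetic scene
    simulate = list(
      solid = "box", size_um = c(220, 220, 140),
      density_per_um3 = 2e-4, labeling_index = 0.5,
      D_pos_um = 6, D_neg_um = 6,
      noise = list(gaussian_sd = 0.02, gradient_amplitude = 0,
                   intensity_jitter = 0)),
    pixel_size_um = 0.9,
    section_thickness_um = 7,
    # detection
    kernel_px = 10L, detection_threshold = NULL, min_area_um2 = 4,
    split_factor = 2, background_window_px = 20L, z_cutoff = 3,
    # segmentation
    segmentation_method = "per_section_auto",
    # measurement
    boxel_size_um = 26, sample_volume_m = 5L,
    required_profiles = 171L,
    min_profiles_for_li = 171L,
    occupancy_threshold = 0.05,
    # QC behavior: warn (advisory) or halt
    strict_qc = FALSE)
  utils::modifyList(cfg, list(...))
}

#' @rdname default_pipeline_config
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  utils::modifyList(default_pipeline_config(), yaml::read_yaml(path))
}

#' @rdname default_pipeline_config
#' @param config a configuration list.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the full quantitative 3D-reconstruction pipeline
#'
#' Orchestrates simulate (or ingest) -> segment -> detect -> split ->
#' classify -> measure -> stereology -> visualize. Every stage leaves a
#' quality-control artifact in the run directory (alignment overlay,
#' segmentation report, nucleus control image, cumulative count
#' distribution) together with a machine-readable verdict; by default QC
#' failures warn and the run continues (the repeat-or-discard decision is
#' the researcher's), while `strict_qc = TRUE` halts at the failing
#' stage. Given the same seed the run is deterministic.
#'
#' @param config a [default_pipeline_config()] list (or path to a YAML
#'   file).
#' @param output_dir run directory, created if needed.
#' @param channels optional pre-made channel list (as returned in
#'   `render_section_stack()$channels`) to ingest instead of simulating;
#'   ground truth is then unavailable and truth-based outputs are
#'   skipped.
#' @return invisibly, a list with the run's main objects: `channels`,
#'   `masks`, `profiles`, `grid`, `raw`, `fields`, `summary`, `qc`.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         output_dir = tempfile("boxel3d_run_"),
                         channels = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(output_dir, "run.log")
  log <- function(...) {
    msg <- sprintf(...)
    cat(format(Sys.time(), "%H:%M:%S "), msg, "\n", sep = "",
        file = logfile, append = TRUE)
  }
  qc <- list()
  fail <- function(stage, verdict, detail) {
    qc[[stage]] <<- list(pass = verdict, detail = detail)
    if (!verdict) {
      msg <- sprintf("QC failed at stage '%s': %s", stage, detail)
      log("%s", msg)
      if (isTRUE(config$strict_qc)) stop(msg, call. = FALSE)
      warning(msg, call. = FALSE)
    } else log("QC '%s' pass: %s", stage, detail)
  }
  t <- config$section_thickness_um
  p <- config$pixel_size_um

  gt <- NULL
  if (is.null(channels)) {
    log("simulating scene (seed %d)", config$seed)
    sim <- config$simulate
    solid <- switch(sim$solid,
      box = solid_box(sim$size_um),
      cylinder = solid_cylinder(sim$size_um[1] / 2, sim$size_um[3],
                                center_xy_um = sim$size_um[1:2] / 2),
      stop("unknown solid type: ", sim$solid))
    gt <- sample_nuclei(solid, sim$density_per_um3, sim$labeling_index,
                        sim$D_pos_um, sim$D_neg_um, seed = config$seed)
    rend <- render_section_stack(gt, t, p, noise = sim$noise)
    channels <- rend$channels
    log("scene: %d nuclei, %d sections", nrow(gt$nuclei),
        n_sections(channels$nuclear))
  }

  # io QC: resolution and substitution rules
  D_min <- min(config$simulate$D_pos_um %||% 6,
               config$simulate$D_neg_um %||% 6)
  res <- validate_resolution(p, D_min)
  fail("resolution", res$ok,
       sprintf("%.2f pixels per nucleus", res$pixels_per_nucleus))
  prov <- channels$nuclear$provenance
  sub <- prov != "original"
  ok_sub <- !any(sub[-1] & sub[-length(sub)])
  fail("substitution", ok_sub,
       sprintf("%d substituted section(s)", sum(sub)))
  if (!ok_sub && !isTRUE(config$strict_qc))
    stop("two adjacent substituted sections: discard the specimen",
         call. = FALSE)

  # alignment QC artifact on a mid-stack pair
  mid <- max(1L, n_sections(channels$nuclear) %/% 2L)
  if (n_sections(channels$nuclear) > 1) {
    ov <- qc_overlay(channels$nuclear$images[[mid]],
                     channels$nuclear$images[[mid + 1L]])
    tiff::writeTIFF(ov, file.path(output_dir, "qc_alignment_overlay.tif"),
                    bits.per.sample = 8L, reduce = FALSE)
  }

  log("segmenting tissue (%s)", config$segmentation_method)
  masks <- segment_tissue(channels$tissue, config$segmentation_method,
                          thresholds = config$segmentation_thresholds)
  seg_qc <- segmentation_qc(masks)
  utils::write.csv(seg_qc$per_section,
                   file.path(output_dir, "qc_segmentation.csv"),
                   row.names = FALSE)
  fail("segmentation", !seg_qc$review_specimen,
       sprintf("%d/%d sections flagged", length(seg_qc$flagged),
               nrow(seg_qc$per_section)))

  log("detecting nuclear profiles (kernel %d px)", config$kernel_px)
  ps <- detect_profiles_stack(channels$nuclear, config$detection_threshold,
                              config$kernel_px, config$min_area_um2)
  ps <- split_large_profiles(ps, config$split_factor)
  ps <- classify_positive(ps, channels$specific$images,
                          config$background_window_px, config$z_cutoff)
  log("%d profiles detected", nrow(ps$profiles))
  ctrl <- control_image(ps, channels$nuclear$images[[mid]],
                        section_index = mid)
  tiff::writeTIFF(ctrl, file.path(output_dir, "qc_control_nuclei.tif"),
                  bits.per.sample = 8L, reduce = FALSE)
  write_profiles(ps, file.path(output_dir, "profiles.csv"))
  fail("detection", nrow(ps$profiles) > 0,
       sprintf("%d profiles", nrow(ps$profiles)))

  log("building boxel grid (%g um)", config$boxel_size_um)
  grid <- build_boxel_grid(ps, masks, config$boxel_size_um, t)
  raw <- measure_sample_volumes(grid, ps, masks, config$sample_volume_m)
  ccd <- cumulative_count_distribution(raw, config$required_profiles)
  utils::write.csv(ccd$curve,
                   file.path(output_dir, "qc_count_distribution.csv"),
                   row.names = FALSE)
  fail("sample_volume", ccd$fraction_below <= 0.5,
       sprintf("%.0f%% of tissue boxels below %d profiles",
               100 * ccd$fraction_below, config$required_profiles))

  log("computing morphogenetic fields")
  params <- stereology_params(t, config$simulate$D_pos_um %||% 6,
                              config$simulate$D_neg_um %||% 6,
                              config$min_profiles_for_li)
  fields <- compute_morpho_fields(raw, params)
  raw1 <- measure_sample_volumes(grid, ps, masks, 1L)
  summary <- pooled_summary(raw1, params)
  if (!is.null(gt)) summary$true_cell_number <- nrow(gt$nuclei)
  jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  log("masking and exporting reconstructions")
  bmask <- downsample_mask_to_boxels(masks, grid,
                                     config$occupancy_threshold)
  for (nm in names(fields)) {
    rec <- mask_field(fields[[nm]], bmask)
    export_reconstruction(rec, file.path(output_dir,
                                         paste0(nm, ".tif")), "tiff")
    export_reconstruction(rec, file.path(output_dir,
                                         paste0(nm, ".vtk")), "vtk")
  }
  jsonlite::write_json(
    lapply(qc, function(x) list(pass = x$pass, detail = x$detail)),
    file.path(output_dir, "qc_verdicts.json"),
    auto_unbox = TRUE, pretty = TRUE)
  log("done")
  invisible(list(channels = channels, masks = masks, profiles = ps,
                 grid = grid, raw = raw, fields = fields,
                 summary = summary, qc = qc, gt = gt,
                 output_dir = output_dir))
}
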
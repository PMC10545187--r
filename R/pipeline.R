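#' Configuration of an end-to-end thickness run
#'
#' Collects everything one sample evaluation needs: the input volume (either
#' a [phantom_spec()] to generate or a directory written by
#' [write_oct_volume()]), the preprocessing block, the interface point source
#' (a sampling-point CSV or auto-seeding parameters), the B-scan selection
#' (y ROI, separation `dy_um`, operator exclusions), optional lateral
#' clipping, and background-noise ROIs.
#'
#' @param sample_id sample identifier carried into all outputs.
#' @param phantom a [phantom_spec()] (used when `volume_dir` is `NULL`).
#' @param volume_dir directory holding `volume.tif` / `volume.json`.
#' @param preprocess a [preprocess_config()].
#' @param points_csv path to a sampling-point CSV; `NULL` enables
#'   auto-seeding.
#' @param seeding named list overriding [auto_seed_interfaces()] defaults
#'   (`n_columns`, `min_gradient`, `rel_gradient`, `gap_opl_um`).
#' @param roi_y_um y range `(lo, hi)` um, half-open; `NULL` = full volume.
#' @param roi_x_um optional lateral clip `(lo, hi)` um for the evaluation.
#' @param dy_um separation between evaluated B-scans (um).
#' @param exclusions 0-based y indices discarded as distorted.
#' @param noise_rois list of [roi_spec()]s measured on the preprocessed
#'   volume.
#' @param i2_raster_density densification factor of the i2 raster.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(sample_id = "sample",
                            phantom = phantom_spec(),
                            volume_dir = NULL,
                            preprocess = preprocess_config(),
                            points_csv = NULL,
                            seeding = list(),
                            roi_y_um = NULL, roi_x_um = NULL,
                            dy_um = 50, exclusions = integer(),
                            noise_rois = list(),
                            i2_raster_density = 4L) {
  if (is.null(phantom) && is.null(volume_dir))
    stop("config needs either a phantom spec or a volume_dir", call. = FALSE)
  seeding_defaults <- list(n_columns = 24L, min_gradient = 0.05,
                           rel_gradient = 0.25, gap_opl_um = 30)
  structure(
    list(sample_id = sample_id, phantom = phantom, volume_dir = volume_dir,
         preprocess = preprocess, points_csv = points_csv,
         seeding = utils::modifyList(seeding_defaults, seeding),
         roi_y_um = roi_y_um, roi_x_um = roi_x_um, dy_um = dy_um,
         exclusions = as.integer(exclusions), noise_rois = noise_rois,
         i2_raster_density = as.integer(i2_raster_density)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Top-level YAML keys map 1:1 onto the [pipeline_config()] arguments;
#' `phantom` and `preprocess` blocks are passed to [phantom_spec()] /
#' [preprocess_config()], and `noise_rois` entries to [roi_spec()].
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y
  if (!is.null(y$phantom)) {
    ph <- y$phantom
    if (!is.null(ph$layers)) ph$layers <- as.data.frame(ph$layers)
    if (!is.null(ph$spacing)) ph$spacing <- unlist(ph$spacing)
    if (!is.null(ph$shape)) ph$shape <- unlist(ph$shape)
    args$phantom <- do.call(phantom_spec, ph)
  }
  if (!is.null(y$preprocess))
    args$preprocess <- do.call(preprocess_config, y$preprocess)
  if (!is.null(y$noise_rois))
    args$noise_rois <- lapply(y$noise_rois, function(r) do.call(roi_spec, r))
  do.call(pipeline_config, args)
}

canonical_config <- function(x) {
  if (is.list(x)) {
    x <- lapply(unclass(x), canonical_config)
    if (!is.null(names(x))) x <- x[order(names(x))]
  }
  x
}

#' Run the full thickness pipeline on one sample
#'
#' Generates or loads the volume, preprocesses it, selects the B-scan set,
#' reconstructs the two bounding interfaces on every included plane,
#' computes the minimum-distance thickness profile in geometric um, reduces
#' it to the per-sample URCL thickness (mean +/- SD over B-scans), and
#' measures any configured background-noise ROIs. The run is deterministic
#' given the configuration (the phantom seed is part of the spec), every
#' stage appends a structured log record, and any stage error aborts with
#' the stage name. When `out_dir` is given, `report.json` and
#' `per_bscan.csv` are written there; reruns with the same configuration
#' produce byte-identical files.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return The report, a list of class `sample_report`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  log <- list()
  note <- function(stage, ...) {
    log[[length(log) + 1L]] <<- c(list(stage = stage), list(...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }

  volume_raw <- stage("load", {
    if (!is.null(config$volume_dir)) read_oct_volume(config$volume_dir)
    else generate_phantom(config$phantom)$volume
  })
  note("load",
       source = if (is.null(config$volume_dir)) "phantom" else config$volume_dir,
       shape = dim(volume_raw$intensity), n_medium = volume_raw$n_medium)

  volume <- stage("preprocess", preprocess_volume(volume_raw, config$preprocess))
  note("preprocess", config = unclass(config$preprocess))

  selection <- stage("select_bscans",
                     select_bscans(volume, config$roi_y_um, config$dy_um,
                                   config$exclusions))
  note("select_bscans", n_bscans = selection$n_bscans, step = selection$step,
       excluded = selection$excluded$y_index)

  manual_points <- if (!is.null(config$points_csv))
    stage("read_points", read_sampling_points(config$points_csv))

  per_bscan <- stage("thickness", {
    rows <- lapply(selection$included, function(yi) {
      pts <- if (!is.null(manual_points)) {
        p <- manual_points[manual_points$y_index == yi, , drop = FALSE]
        if (nrow(p) == 0L)
          stop("no sampling points for y_index ", yi, call. = FALSE)
        p
      } else {
        s <- config$seeding
        auto_seed_interfaces(bscan_plane(volume, yi), volume$spacing,
                             y_index = yi, n_columns = s$n_columns,
                             min_gradient = s$min_gradient,
                             rel_gradient = s$rel_gradient,
                             gap_opl_um = s$gap_opl_um,
                             sample_id = config$sample_id)
      }
      raster <- rasterize_curves(fit_interface(pts, "i1"),
                                 fit_interface(pts, "i2"),
                                 n_medium = volume$n_medium,
                                 spacing_x = volume$spacing[["x"]],
                                 density = config$i2_raster_density,
                                 x_range = config$roi_x_um)
      prof <- thickness_profile(raster)
      s <- bscan_mean_thickness(prof)
      data.frame(y_index = yi, t_b = s$t_b, sd_b = s$sd_b, m = s$m,
                 n_endpoint_flagged = sum(prof$endpoint_flag))
    })
    do.call(rbind, rows)
  })
  note("thickness", m = per_bscan$m, n_bscans = nrow(per_bscan))

  summary <- stage("sample_thickness", sample_thickness(per_bscan$t_b))
  note("sample_thickness", t_urcl = summary$t_urcl, sd_urcl = summary$sd_urcl)

  noise <- stage("background_noise", {
    lapply(config$noise_rois, function(roi) {
      rep <- background_noise(bscan_plane(volume, roi$y_index), roi,
                              provenance = list(
                                preprocess = unclass(config$preprocess)))
      list(tag = roi$tag, y_index = roi$y_index, sigma_bg = rep$sigma_bg,
           n_voxels = rep$n_voxels)
    })
  })
  if (length(noise)) note("background_noise",
                          sigma_bg = vapply(noise, `[[`, 0, "sigma_bg"))

  report <- structure(
    list(
      sample_id = config$sample_id,
      software = "octlayer",
      version = as.character(utils::packageVersion("octlayer")),
      config_hash = rlang::hash(canonical_config(config)),
      n_medium = volume$n_medium,
      dy_um = config$dy_um,
      step_voxels = selection$step,
      n_bscans = summary$n_bscans,
      included = selection$included,
      excluded = selection$excluded,
      per_bscan = per_bscan,
      t_urcl = summary$t_urcl,
      sd_urcl = summary$sd_urcl,
      single_bscan = summary$single_bscan,
      noise = noise,
      seed = if (is.null(config$volume_dir)) config$phantom$seed,
      log = log
    ),
    class = "sample_report"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    utils::write.csv(per_bscan, file.path(out_dir, "per_bscan.csv"),
                     row.names = FALSE)
  }
  report
}

#' @export
print.sample_report <- function(x, ...) {
  cat(sprintf("<sample_report> %s: t_URCL = %.2f +/- %.2f um (N_B-scans = %d)\n",
              x$sample_id, x$t_urcl, x$sd_urcl, x$n_bscans))
  invisible(x)
}
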
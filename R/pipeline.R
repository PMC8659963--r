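default_config <- function() {
  list(
    layout = list(n_trays = 12, tray_length_mm = 640, tray_width_mm = 400,
                  tray_height_mm = 425, frame_width_mm = 20),
    soil = list(method = "rgs", k_neighbors = 30, angle_deg = 3,
                curvature_threshold = 1, min_cluster_size = 50,
                ransac_threshold_mm = 2.5, ransac_iterations = 1000, seed = 1),
    raster = list(pixel_size_mm = 0.8, sor_k = 16, sor_std = 2),
    detector = list(backend = "baseline", min_area_px = 30, area_ref_px = 500,
                    iou_threshold = 0.2, score_threshold = 0.5,
                    max_detections = 10, aspect_ratios = c(0.5, 1, 2),
                    external_path = NULL)
  )
}

#' Pipeline configuration
#'
#' Builds the nested configuration driving [run_pipeline()], starting from
#' documented defaults and overriding with any supplied values. Unknown
#' keys are rejected. Sections and keys:
#' \describe{
#'   \item{layout}{`n_trays` (12), `tray_length_mm` (640), `tray_width_mm`
#'     (400), `tray_height_mm` (425), `frame_width_mm` (20).}
#'   \item{soil}{`method` ("rgs" or "ransac"), `k_neighbors` (30),
#'     `angle_deg` (3), `curvature_threshold` (1), `min_cluster_size` (50),
#'     `ransac_threshold_mm` (2.5), `ransac_iterations` (1000), `seed` (1).}
#'   \item{raster}{`pixel_size_mm` (0.8), `sor_k` (16), `sor_std` (2).}
#'   \item{detector}{`backend` ("baseline" or "external"), `min_area_px`
#'     (30), `area_ref_px` (500), `iou_threshold` (0.2), `score_threshold`
#'     (0.5), `max_detections` (10), `aspect_ratios` (0.5, 1, 2),
#'     `external_path` (CSV of external detections).}
#' }
#'
#' @param ... Named sections (`layout`, `soil`, `raster`, `detector`), each
#'   a list of keys to override.
#' @return A `pipeline_config` nested list.
#' @examples
#' pipeline_config(soil = list(method = "ransac"), layout = list(n_trays = 6))
#' @export
pipeline_config <- function(...) {
  over <- list(...)
  cfg <- default_config()
  bad_sections <- setdiff(names(over), names(cfg))
  if (length(bad_sections)) {
    abort(sprintf("unknown config sections: %s", paste(bad_sections, collapse = ", ")))
  }
  for (sec in names(over)) {
    vals <- over[[sec]]
    bad <- setdiff(names(vals), names(cfg[[sec]]))
    if (length(bad)) {
      abort(sprintf("unknown keys in %s: %s", sec, paste(bad, collapse = ", ")))
    }
    cfg[[sec]][names(vals)] <- vals
  }
  stopifnot(cfg$soil$method %in% c("rgs", "ransac"),
            cfg$detector$backend %in% c("baseline", "external"),
            cfg$raster$pixel_size_mm > 0)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Values present in the file override the defaults of [pipeline_config()];
#' unknown keys are rejected.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(pipeline_config, raw)
}

#' Write the effective configuration
#' @param cfg A `pipeline_config`.
#' @param path Output `.yaml` path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the five-step plant-counting pipeline on a raw scan
#'
#' Executes, per tray: frame removal, soil segmentation
#' ([extract_plants()]), statistical outlier removal, rasterization,
#' detection (baseline connected-component detector or externally supplied
#' detections), post-filtering and counting. A failure in one tray is
#' recorded in that tray's `error` field and does not stop the others.
#' With the same configuration and input the result is bit-identical
#' across runs (all randomness is seeded from the config).
#'
#' @param cloud A raw scan-row point-cloud tibble, or a path to a PLY/XYZ
#'   file readable by [read_cloud()].
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory; when given, per-tray PNGs, a
#'   detections CSV, a counts CSV and the effective config are written.
#' @param verbose Log per-stage point/box counts via [message()] (default
#'   `FALSE`).
#' @return A `pipeline_result`: list with `trays` (per-tray tibble of stage
#'   counts, plant count and error), `detections` (combined filtered
#'   detection tibble), `images` (named list of `raster_image`s) and
#'   `config`.
#' @export
run_pipeline <- function(cloud, config = pipeline_config(), out_dir = NULL,
                         verbose = FALSE) {
  if (is.character(cloud)) cloud <- read_cloud(cloud)
  lay <- do.call(tray_layout, config$layout)
  trays <- split_trays(cloud, lay)
  log_msg <- function(...) if (verbose) message(sprintf(...))
  log_msg("split %d points into %d trays", nrow(cloud), lay$n_trays)

  soil_params <- if (config$soil$method == "rgs") {
    rgs_params(k_neighbors = config$soil$k_neighbors,
               angle_threshold_deg = config$soil$angle_deg,
               curvature_threshold = config$soil$curvature_threshold,
               min_cluster_size = config$soil$min_cluster_size)
  } else {
    list(distance_threshold_mm = config$soil$ransac_threshold_mm,
         max_iterations = config$soil$ransac_iterations,
         rng_seed = config$soil$seed)
  }
  det_cfg <- detector_config(
    aspect_ratios = config$detector$aspect_ratios,
    iou_threshold = config$detector$iou_threshold,
    score_threshold = config$detector$score_threshold,
    max_detections_per_class = config$detector$max_detections)

  images <- list()
  det_list <- list()
  rows <- vector("list", lay$n_trays)
  for (t in seq_len(lay$n_trays)) {
    id <- tray_image_id(t)
    res <- tryCatch({
      tray <- trays[[t]]
      clean <- remove_frame(tray, lay)
      extent <- if (nrow(clean)) c(range(clean$x), range(clean$y)) else c(0, 1, 0, 1)
      plants <- extract_plants(clean, method = config$soil$method,
                               params = soil_params)
      denoised <- if (nrow(plants) > config$raster$sor_k) {
        sor_filter(plants, config$raster$sor_k, config$raster$sor_std)
      } else plants
      img <- rasterize(denoised, config$raster$pixel_size_mm, extent)
      dets <- if (config$detector$backend == "baseline") {
        baseline_detect(img, config$detector$min_area_px,
                        config$detector$area_ref_px, image_id = id)
      } else {
        if (is.null(config$detector$external_path)) {
          abort("detector.backend = 'external' needs detector.external_path")
        }
        load_external_detections(config$detector$external_path, image_id = id)
      }
      dets <- filter_detections(dets, det_cfg)
      log_msg("%s: %d raw -> %d frame-cleaned -> %d plant -> %d denoised points; %d detections",
              id, nrow(tray), nrow(clean), nrow(plants), nrow(denoised), nrow(dets))
      n_raw_pts <- nrow(tray)
      list(img = img, dets = dets,
           row = tibble::tibble(
             tray = t, image_id = id, n_raw = n_raw_pts,
             n_frame_cleaned = nrow(clean), n_plant_points = nrow(plants),
             n_denoised = nrow(denoised), n_detections = nrow(dets),
             count = count_plants(dets), error = NA_character_))
    }, error = function(e) {
      list(img = NULL, dets = NULL,
           row = tibble::tibble(
             tray = t, image_id = id, n_raw = nrow(trays[[t]]),
             n_frame_cleaned = NA_integer_, n_plant_points = NA_integer_,
             n_denoised = NA_integer_, n_detections = NA_integer_,
             count = NA_integer_, error = conditionMessage(e)))
    })
    if (!is.null(res$img)) images[[id]] <- res$img
    if (!is.null(res$dets) && nrow(res$dets)) det_list[[id]] <- res$dets
    rows[[t]] <- res$row
  }
  detections <- if (length(det_list)) {
    as_boxes(dplyr::bind_rows(lapply(det_list, tibble::as_tibble)))
  } else empty_detections()
  result <- structure(list(trays = dplyr::bind_rows(rows),
                           detections = detections, images = images,
                           config = config),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  ok <- is.na(x$trays$error)
  cat(sprintf("<pipeline_result> %d trays (%d ok), %d detections, %s plants total\n",
              nrow(x$trays), sum(ok), nrow(x$detections),
              sum(x$trays$count, na.rm = TRUE)))
  invisible(x)
}

#' Per-tray summary of a pipeline result
#' @param x A `pipeline_result`.
#' @param ... Unused.
#' @return The per-tray stage-count tibble.
#' @export
tidy.pipeline_result <- function(x, ...) x$trays

#' Write pipeline outputs to a directory
#'
#' Writes per-tray PNG rasters (with geometry sidecars), the filtered
#' detections CSV, the per-tray counts CSV and the effective config YAML.
#'
#' @param result A `pipeline_result`.
#' @param out_dir Directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(result$images)) {
    write_raster_png(result$images[[id]], file.path(out_dir, paste0(id, ".png")))
  }
  write_annotations(result$detections, file.path(out_dir, "detections.csv"))
  write.csv(as.data.frame(result$trays[c("tray", "image_id", "count", "error")]),
            file.path(out_dir, "counts.csv"), row.names = FALSE)
  write_pipeline_config(result$config, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

#' Evaluate a pipeline result against ground truth
#'
#' Ground truth can be a `scene_truth` from [generate_scene()] (plant
#' footprints are projected into each tray's raster geometry) or an
#' annotation tibble already in pixel coordinates plus the per-tray manual
#' counts it implies. Produces the full [evaluate_detections()] report:
#' precision/recall at IoU 0.5, AP per IoU threshold, COCO mAP, per-tray
#' counts and MAPE.
#'
#' @param result A `pipeline_result`.
#' @param truth A `scene_truth` or an annotation tibble with `image_id`s
#'   matching the result's trays.
#' @return A `metrics_report`.
#' @export
evaluate_pipeline <- function(result, truth) {
  ids <- result$trays$image_id
  if (inherits(truth, "scene_truth")) {
    unmatched <- setdiff(truth$per_tray$image_id, ids)
    if (length(unmatched)) {
      abort(sprintf("truth trays missing from result: %s",
                    paste(unmatched, collapse = ", ")))
    }
    gts <- truth_to_annotations(truth, result$images)
  } else {
    gts <- truth
    unmatched <- setdiff(unique(gts$image_id), ids)
    if (length(unmatched)) {
      abort(sprintf("annotation image_ids missing from result: %s",
                    paste(unmatched, collapse = ", ")))
    }
  }
  evaluate_detections(result$detections, gts, tray_ids = ids)
}
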
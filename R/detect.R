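#' Detector configuration
#'
#' Carries the post-processing configuration applied to any detector's raw
#' output: the minimum confidence kept, the overlap threshold for greedy
#' suppression of duplicate boxes, and the per-class detection cap (the
#' platform holds only a handful of plants per tray). `aspect_ratios`
#' parameterise the region proposals of CNN detectors; they are stored and
#' validated but unused by the classical baseline detector.
#'
#' @param aspect_ratios Proposal side ratios, default `c(0.5, 1, 2)`.
#' @param iou_threshold Boxes overlapping an accepted box by more than this
#'   IoU are suppressed (default 0.2).
#' @param score_threshold Minimum confidence kept (default 0.5).
#' @param max_detections_per_class Cap per class after filtering (default 10).
#' @return A `detector_config` list.
#' @export
detector_config <- function(aspect_ratios = c(0.5, 1, 2), iou_threshold = 0.2,
                            score_threshold = 0.5, max_detections_per_class = 10) {
  stopifnot(all(aspect_ratios > 0),
            iou_threshold >= 0, iou_threshold <= 1,
            score_threshold >= 0, score_threshold <= 1,
            max_detections_per_class >= 1)
  structure(list(aspect_ratios = aspect_ratios,
                 iou_threshold = iou_threshold,
                 score_threshold = score_threshold,
                 max_detections_per_class = as.integer(max_detections_per_class)),
            class = "detector_config")
}

#' Baseline connected-component plant detector
#'
#' A classical detector operating directly on the rasterized image: plant
#' pixels (anything not equal to the reserved background) are labelled into
#' 8-connected components and each component of at least `min_area_px`
#' pixels becomes one box. The confidence is `min(1, area / area_ref_px)`,
#' so fragments score low and full plants saturate at 1. This detector
#' plugs into the same post-filtering as any externally trained CNN
#' detector (see [load_external_detections()]).
#'
#' @param image A `raster_image`.
#' @param min_area_px Minimum component area in pixels (default 30).
#' @param area_ref_px Area at which the confidence saturates (default 500).
#' @param image_id Identifier stored in the output (default `"image"`).
#' @return A detection tibble (class `cc_boxes`) sorted by score descending,
#'   columns `image_id`, `label`, `x_min`, `y_min`, `x_max`, `y_max`,
#'   `score`; half-open pixel coordinates with the origin at the minimal-y
#'   corner of the raster.
#' @export
baseline_detect <- function(image, min_area_px = 30, area_ref_px = 500,
                            image_id = "image") {
  stopifnot(inherits(image, "raster_image"), min_area_px >= 1, area_ref_px > 0)
  lab <- .cc_label_components(plant_mask(image))
  m <- max(lab)
  if (m == 0L) return(empty_detections())
  comp <- lapply(seq_len(m), function(i) which(lab == i, arr.ind = TRUE))
  area <- vapply(comp, nrow, integer(1))
  keep <- which(area >= min_area_px)
  if (!length(keep)) return(empty_detections())
  boxes <- tibble::tibble(
    image_id = image_id,
    label = "plant",
    x_min = vapply(comp[keep], function(m) min(m[, "col"]) - 1, numeric(1)),
    y_min = vapply(comp[keep], function(m) min(m[, "row"]) - 1, numeric(1)),
    x_max = vapply(comp[keep], function(m) max(m[, "col"]), numeric(1)),
    y_max = vapply(comp[keep], function(m) max(m[, "row"]), numeric(1)),
    score = pmin(1, area[keep] / area_ref_px)
  )
  boxes <- boxes[order(-boxes$score), ]     # stable: ties keep label order
  sz <- raster_size(image)
  as_boxes(boxes, image_width = sz[["width"]], image_height = sz[["height"]])
}

empty_detections <- function() {
  as_boxes(tibble::tibble(image_id = character(), label = character(),
                          x_min = numeric(), y_min = numeric(),
                          x_max = numeric(), y_max = numeric(),
                          score = numeric()))
}

#' Post-filter detections: score gate, greedy suppression, per-class cap
#'
#' Applies, in order: (1) drop boxes scoring below
#' `cfg$score_threshold`; (2) greedy non-maximum suppression in descending
#' score order — a box is rejected when its IoU with any already-accepted
#' box of the same image exceeds `cfg$iou_threshold`; (3) keep at most
#' `cfg$max_detections_per_class` boxes per image and class. The function is
#' idempotent. Score ties are broken by input order.
#'
#' @param dets A detection tibble with a `score` column (any order; sorted
#'   internally).
#' @param cfg A [detector_config()].
#' @return The filtered detection tibble, sorted by score descending.
#' @export
filter_detections <- function(dets, cfg = detector_config()) {
  stopifnot("score" %in% names(dets))
  dets <- dets[order(-dets$score), ]
  dets <- dets[dets$score >= cfg$score_threshold, , drop = FALSE]
  if (!nrow(dets)) return(as_boxes(tibble::as_tibble(dets)))
  keep_rows <- unlist(lapply(
    split(seq_len(nrow(dets)), paste(dets$image_id, dets$label, sep = "\r")),
    function(rows) {
      rows <- sort(rows)                      # score order within group
      accepted <- integer()
      for (i in rows) {
        if (length(accepted)) {
          ious <- bbox_iou(dets[rep(i, length(accepted)), ], dets[accepted, ])
          if (any(ious > cfg$iou_threshold)) next
        }
        accepted <- c(accepted, i)
        if (length(accepted) >= cfg$max_detections_per_class) break
      }
      accepted
    }), use.names = FALSE)
  out <- dets[sort(keep_rows), , drop = FALSE]
  as_boxes(tibble::as_tibble(out))
}

#' Load externally produced detections from CSV
#'
#' Adapter so detections exported by any trained detector (e.g. a
#' fine-tuned CNN) can enter the post-filtering and evaluation stages. The
#' CSV uses the shared annotation dialect with a mandatory `score` column.
#'
#' @param path CSV path with header
#'   `image_id,label,x_min,y_min,x_max,y_max,score`.
#' @param image_id Optional filter: keep only rows of this image.
#' @return A detection tibble sorted by score descending.
#' @export
load_external_detections <- function(path, image_id = NULL) {
  dets <- read_annotations(path, format = "csv")
  if (!"score" %in% names(dets)) {
    abort(sprintf("detections file %s lacks a score column", basename(path)))
  }
  if (!is.null(image_id)) dets <- dets[dets$image_id == image_id, , drop = FALSE]
  as_boxes(tibble::as_tibble(dets[order(-dets$score), , drop = FALSE]))
}
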
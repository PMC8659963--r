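#' Intersection over union of axis-aligned boxes
#'
#' Boxes are half-open pixel rectangles, so areas and overlaps are exact
#' rectangle algebra: IoU = area(a intersect b) / area(a union b).
#'
#' @param a,b Box tibbles (columns `x_min`, `y_min`, `x_max`, `y_max`);
#'   rows are paired, with the shorter recycled if of length 1.
#' @return Numeric vector of IoU values in \[0, 1\].
#' @examples
#' bbox_iou(tibble::tibble(x_min = 0, y_min = 0, x_max = 2, y_max = 2),
#'          tibble::tibble(x_min = 1, y_min = 0, x_max = 3, y_max = 2))
#' @export
bbox_iou <- function(a, b) {
  iw <- pmax(0, pmin(a$x_max, b$x_max) - pmax(a$x_min, b$x_min))
  ih <- pmax(0, pmin(a$y_max, b$y_max) - pmax(a$y_min, b$y_min))
  inter <- iw * ih
  area_a <- (a$x_max - a$x_min) * (a$y_max - a$y_min)
  area_b <- (b$x_max - b$x_min) * (b$y_max - b$y_min)
  inter / (area_a + area_b - inter)
}

#' Match detections to ground truth at an IoU threshold
#'
#' Detections are taken in descending score order (within each image);
#' each one is matched to the still-unmatched ground-truth box with the
#' highest IoU, provided that IoU is strictly greater than `iou_thresh`
#' (a tie with the threshold does not count as a match). IoU ties between
#' ground-truth boxes go to the lower ground-truth index. Unmatched
#' detections are false positives, unmatched ground truth false negatives.
#'
#' @param dets Detection tibble with `score` (sorted internally).
#' @param gts Ground-truth box tibble. When both carry `image_id`, matching
#'   is per image.
#' @param iou_thresh IoU threshold (default 0.5).
#' @return A `match_result`: list with `tp`, `fp`, `fn`, `matched_pairs`
#'   (tibble of `det`, `gt` row indices into the inputs and the pair `iou`),
#'   and `det_is_tp` (logical, one flag per input detection row).
#' @export
match_detections <- function(dets, gts, iou_thresh = 0.5) {
  n_det <- nrow(dets); n_gt <- nrow(gts)
  det_order <- order(-dets$score)
  gt_used <- rep(FALSE, n_gt)
  det_is_tp <- rep(FALSE, n_det)
  pairs_det <- integer(); pairs_gt <- integer(); pairs_iou <- numeric()
  use_images <- "image_id" %in% names(dets) && "image_id" %in% names(gts)
  for (i in det_order) {
    cand <- if (n_gt) which(!gt_used) else integer()
    if (use_images && length(cand)) {
      cand <- cand[gts$image_id[cand] == dets$image_id[i]]
    }
    if (!length(cand)) next
    ious <- bbox_iou(dets[rep(i, length(cand)), ], gts[cand, ])
    best <- which.max(ious)                 # ties -> lower gt index
    if (ious[best] > iou_thresh) {
      g <- cand[best]
      gt_used[g] <- TRUE
      det_is_tp[i] <- TRUE
      pairs_det <- c(pairs_det, i); pairs_gt <- c(pairs_gt, g)
      pairs_iou <- c(pairs_iou, ious[best])
    }
  }
  structure(list(
    tp = sum(det_is_tp), fp = n_det - sum(det_is_tp), fn = n_gt - sum(gt_used),
    matched_pairs = tibble::tibble(det = pairs_det, gt = pairs_gt, iou = pairs_iou),
    det_is_tp = det_is_tp),
    class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> TP %d, FP %d, FN %d\n", x$tp, x$fp, x$fn))
  invisible(x)
}

#' Precision and recall of a match result
#'
#' Precision = TP / (TP + FP), the fraction of detections that are real
#' plants; recall = TP / (TP + FN), the fraction of plants found. A zero
#' denominator yields 0 with a warning.
#'
#' @param m A [match_detections()] result.
#' @return Named numeric vector `c(precision, recall)`.
#' @export
precision_recall <- function(m) {
  p <- if (m$tp + m$fp > 0) m$tp / (m$tp + m$fp) else {
    warn("precision undefined (no detections); reporting 0"); 0
  }
  r <- if (m$tp + m$fn > 0) m$tp / (m$tp + m$fn) else {
    warn("recall undefined (no ground truth); reporting 0"); 0
  }
  c(precision = p, recall = r)
}

#' Average precision at one IoU threshold (101-point interpolation)
#'
#' Detections are swept in descending score order, accumulating a
#' precision-recall curve whose correctness flags come from the greedy
#' matching of [match_detections()]. AP is the mean of the interpolated
#' precision `max(P at recall >= r)` over the 101 recall anchors
#' r = 0, 0.01, ..., 1.
#'
#' @inheritParams match_detections
#' @return AP in \[0, 1\]; 0 with a warning when there is no ground truth.
#' @export
average_precision <- function(dets, gts, iou_thresh = 0.5) {
  if (!nrow(gts)) {
    warn("average_precision undefined without ground truth; reporting 0")
    return(0)
  }
  if (!nrow(dets)) return(0)
  m <- match_detections(dets, gts, iou_thresh)
  o <- order(-dets$score)
  tp_cum <- cumsum(m$det_is_tp[o])
  fp_cum <- cumsum(!m$det_is_tp[o])
  prec <- tp_cum / (tp_cum + fp_cum)
  rec <- tp_cum / nrow(gts)
  anchors <- seq(0, 1, by = 0.01)
  interp <- vapply(anchors, function(r) {
    ok <- rec >= r
    if (any(ok)) max(prec[ok]) else 0
  }, numeric(1))
  mean(interp)
}

#' COCO-style mean average precision
#'
#' The mean of [average_precision()] over the ten IoU thresholds
#' 0.50, 0.55, ..., 0.95.
#'
#' @inheritParams match_detections
#' @return Named list with `map_coco` and `ap_by_threshold` (named vector).
#' @export
map_coco <- function(dets, gts) {
  thresholds <- seq(0.5, 0.95, by = 0.05)
  ap <- vapply(thresholds, function(t) average_precision(dets, gts, t), numeric(1))
  names(ap) <- sprintf("%.2f", thresholds)
  list(map_coco = mean(ap), ap_by_threshold = ap)
}

#' Count plant detections
#'
#' @param dets A filtered detection tibble.
#' @param label Class counted (default `"plant"`).
#' @return Integer count.
#' @export
count_plants <- function(dets, label = "plant") {
  if (!nrow(dets)) return(0L)
  sum(dets$label == label)
}

#' Mean absolute percentage error of per-tray counts
#'
#' MAPE = (100 / n) * sum over trays of
#' |predicted - manual| / manual, over trays with a positive manual count.
#' Trays whose manual count is zero cannot enter the ratio; they are
#' excluded from n and reported via the `zero_truth_fp` attribute (total
#' predictions on zero-truth trays, i.e. false detections on empty trays).
#' Counting accuracy is conventionally reported as 100 - MAPE.
#'
#' @param per_tray Tibble with columns `predicted` and `manual` (one row per
#'   tray).
#' @return MAPE in percent, with attributes `n_trays_counted` and
#'   `zero_truth_fp`.
#' @examples
#' mape(tibble::tibble(predicted = c(3, 5, 6), manual = c(4, 5, 5)))
#' @export
mape <- function(per_tray) {
  stopifnot(all(c("predicted", "manual") %in% names(per_tray)))
  pos <- per_tray$manual > 0
  if (!any(pos)) abort("MAPE undefined: every tray has a zero manual count")
  err <- abs(per_tray$predicted[pos] - per_tray$manual[pos]) / per_tray$manual[pos]
  out <- 100 * sum(err) / sum(pos)
  attr(out, "n_trays_counted") <- sum(pos)
  attr(out, "zero_truth_fp") <- sum(per_tray$predicted[!pos])
  out
}

#' Full detection and counting report
#'
#' Combines matching quality at IoU 0.5 (precision, recall), the COCO mAP
#' sweep, and per-tray count accuracy (MAPE, accuracy = 100 - MAPE) into
#' one report. Images and trays are identified by `image_id`.
#'
#' @param dets Detection tibble over all images (with `image_id`, `score`).
#' @param gts Ground-truth box tibble over all images (with `image_id`).
#' @param tray_ids Optional character vector of all tray ids, so trays with
#'   neither detections nor ground truth still appear with counts 0.
#' @return A `metrics_report` object; see [tidy.metrics_report()] and
#'   [glance.metrics_report()].
#' @export
evaluate_detections <- function(dets, gts, tray_ids = NULL) {
  ids <- tray_ids %||% sort(unique(c(dets$image_id, gts$image_id)))
  if (!length(ids)) abort("no trays to evaluate")
  missing_ids <- setdiff(unique(c(dets$image_id, gts$image_id)), ids)
  if (length(missing_ids)) {
    abort(sprintf("tray ids not in tray_ids: %s", paste(missing_ids, collapse = ", ")))
  }
  m05 <- match_detections(dets, gts, 0.5)
  pr <- suppressWarnings(precision_recall(m05))
  mc <- map_coco(dets, gts)
  per_tray <- tibble::tibble(
    tray = ids,
    predicted = vapply(ids, function(i) count_plants(dets[dets$image_id == i, ]),
                       integer(1), USE.NAMES = FALSE),
    manual = vapply(ids, function(i) sum(gts$image_id == i),
                    integer(1), USE.NAMES = FALSE)
  )
  mp <- if (any(per_tray$manual > 0)) mape(per_tray) else NA_real_
  structure(list(
    precision = unname(pr["precision"]), recall = unname(pr["recall"]),
    ap_by_threshold = mc$ap_by_threshold, map_coco = mc$map_coco,
    per_tray_counts = per_tray,
    mape_percent = as.numeric(mp),
    accuracy_percent = 100 - as.numeric(mp),
    zero_truth_fp = attr(mp, "zero_truth_fp") %||% sum(per_tray$predicted[per_tray$manual == 0]),
    n_trays = length(ids)),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %d trays\n", x$n_trays))
  cat(sprintf("  precision %.3f  recall %.3f  (IoU 0.5)\n", x$precision, x$recall))
  cat(sprintf("  mAP[0.50:0.95] %.3f\n", x$map_coco))
  cat(sprintf("  MAPE %.2f%%  (counting accuracy %.2f%%), %d false detections on empty trays\n",
              x$mape_percent, x$accuracy_percent, x$zero_truth_fp))
  invisible(x)
}

#' Per-tray counts of a metrics report
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return Tibble with `tray`, `predicted`, `manual` and the per-tray
#'   absolute percentage error (`ape_percent`, NA on zero-truth trays).
#' @export
tidy.metrics_report <- function(x, ...) {
  dplyr::mutate(x$per_tray_counts,
                ape_percent = ifelse(.data$manual > 0,
                                     100 * abs(.data$predicted - .data$manual) / .data$manual,
                                     NA_real_))
}

#' One-row summary of a metrics report
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return One-row tibble with precision, recall, mAP, MAPE, accuracy,
#'   zero-truth false positives and tray count.
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(precision = x$precision, recall = x$recall,
                 map_coco = x$map_coco, mape_percent = x$mape_percent,
                 accuracy_percent = x$accuracy_percent,
                 zero_truth_fp = x$zero_truth_fp, n_trays = x$n_trays)
}

#' Write a metrics report to JSON and per-tray CSV
#'
#' @param report A `metrics_report`.
#' @param json_path,csv_path Output paths (either may be `NULL` to skip).
#' @return `report`, invisibly.
#' @export
write_metrics <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(precision = report$precision, recall = report$recall,
           ap_by_threshold = as.list(report$ap_by_threshold),
           map_coco = report$map_coco, mape_percent = report$mape_percent,
           accuracy_percent = report$accuracy_percent,
           zero_truth_fp = report$zero_truth_fp, n_trays = report$n_trays),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    write.csv(as.data.frame(tidy(report)), csv_path, row.names = FALSE)
  }
  invisible(report)
}
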
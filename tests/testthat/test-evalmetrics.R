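box <- function(x0, y0, x1, y1, score = NULL, id = "t") {
  out <- tibble::tibble(image_id = id, label = "plant",
                        x_min = x0, y_min = y0, x_max = x1, y_max = y1)
  if (!is.null(score)) out$score <- score
  out
}

test_that("IoU handles identity, disjointness and partial overlap exactly", {
  a <- box(0, 0, 2, 2)
  expect_equal(bbox_iou(a, a), 1)
  expect_equal(bbox_iou(a, box(5, 5, 7, 7)), 0)
  expect_equal(bbox_iou(a, box(1, 0, 3, 2)), 1 / 3)   # inter 2, union 6
})

test_that("IoU matches integer-pixel enumeration on random boxes and is symmetric", {
  set.seed(71)
  for (rep in 1:20) {
    a <- random_boxes(1, scores = FALSE)
    b <- random_boxes(1, scores = FALSE)
    expect_equal(bbox_iou(a, b), oracle_iou_pixels(a, b), tolerance = 1e-15)
    expect_identical(bbox_iou(a, b), bbox_iou(b, a))
  }
})

test_that("matching handles the trivial perfect and empty cases", {
  gt <- box(0, 0, 10, 10)
  m <- match_detections(box(0, 0, 10, 10, score = 0.9), gt, 0.5)
  expect_equal(c(m$tp, m$fp, m$fn), c(1, 0, 0))
  m0 <- match_detections(box(0, 0, 1, 1, score = 1)[0, ],
                         dplyr::bind_rows(gt, box(20, 0, 30, 10), box(0, 20, 10, 30)),
                         0.5)
  expect_equal(c(m0$tp, m0$fp, m0$fn), c(0, 0, 3))
})

test_that("IoU exactly at the threshold is not a match (strict inequality)", {
  gt <- box(0, 0, 10, 10)
  det <- box(0, 0, 10, 6, score = 0.9)        # IoU exactly 0.6
  expect_equal(bbox_iou(det, gt), 0.6)
  expect_equal(match_detections(det, gt, 0.6)$tp, 0)
  expect_equal(match_detections(det, gt, 0.59)$tp, 1)
})

test_that("greedy matching equals a plain-loop oracle on random small scenes", {
  set.seed(72)
  for (rep in 1:40) {
    dets <- random_boxes(sample(0:8, 1))
    gts <- random_boxes(sample(0:8, 1), scores = FALSE)
    thr <- sample(c(0.2, 0.5, 0.75), 1)
    m <- match_detections(dets, gts, thr)
    o <- oracle_match(dets, gts, thr)
    expect_identical(c(m$tp, m$fp, m$fn), c(o$tp, o$fp, o$fn))
    expect_identical(m$det_is_tp, o$det_is_tp)
  }
})

test_that("precision and recall follow their defining ratios", {
  m <- list(tp = 3, fp = 0, fn = 0)
  expect_equal(unname(precision_recall(m)), c(1, 1))
  m <- list(tp = 1, fp = 1, fn = 1)
  expect_equal(unname(precision_recall(m)), c(0.5, 0.5))
  set.seed(73)
  for (rep in 1:10) {
    m <- list(tp = sample(1:9, 1), fp = sample(0:9, 1), fn = sample(0:9, 1))
    pr <- precision_recall(m)
    expect_equal(unname(pr["precision"]), m$tp / (m$tp + m$fp))
    expect_equal(unname(pr["recall"]), m$tp / (m$tp + m$fn))
  }
  expect_warning(pr0 <- precision_recall(list(tp = 0, fp = 0, fn = 2)), "precision")
  expect_equal(unname(pr0["precision"]), 0)
})

test_that("average precision: trivial cases and staircase-oracle equality", {
  gt <- box(0, 0, 10, 10)
  expect_equal(average_precision(box(0, 0, 10, 10, score = 1), gt, 0.5), 1)
  expect_equal(average_precision(random_boxes(0), gt, 0.5), 0)
  expect_warning(ap <- average_precision(box(0, 0, 5, 5, score = 1),
                                         random_boxes(0, scores = FALSE), 0.5),
                 "ground truth")
  expect_equal(ap, 0)
  set.seed(74)
  for (rep in 1:30) {
    dets <- random_boxes(sample(1:6, 1))
    gts <- random_boxes(sample(1:4, 1), scores = FALSE)
    thr <- sample(c(0.3, 0.5, 0.7), 1)
    expect_equal(average_precision(dets, gts, thr), oracle_ap(dets, gts, thr),
                 tolerance = 1e-12)
  }
})

test_that("mAP over the ten thresholds: perfect, staircase at 0.6, empty", {
  gt <- box(0, 0, 10, 10)
  expect_equal(map_coco(box(0, 0, 10, 10, score = 1), gt)$map_coco, 1)
  # IoU exactly 0.6: counted only at thresholds 0.50 and 0.55 -> mAP 0.2
  mc <- map_coco(box(0, 0, 10, 6, score = 0.9), gt)
  expect_equal(unname(mc$ap_by_threshold), c(1, 1, rep(0, 8)))
  expect_equal(mc$map_coco, 0.2)
  expect_equal(map_coco(random_boxes(0), gt)$map_coco, 0)
  # per-term monotonicity: stricter thresholds never increase AP
  set.seed(75)
  for (rep in 1:10) {
    ap <- map_coco(random_boxes(6), random_boxes(4, scores = FALSE))$ap_by_threshold
    expect_true(all(diff(ap) <= 1e-12))
  }
})

test_that("plant counting is the cardinality of plant-labelled boxes", {
  expect_equal(count_plants(random_boxes(0)), 0L)
  dets <- random_boxes(4)
  expect_equal(count_plants(dets), 4L)
  dets$label[2] <- "weed"
  expect_equal(count_plants(dets), 3L)
})

test_that("MAPE follows its per-tray formula and excludes zero-truth trays", {
  exact <- tibble::tibble(predicted = c(2, 0, 7), manual = c(2, 0, 7))
  expect_equal(as.numeric(mape(exact)), 0)
  one <- tibble::tibble(predicted = 11, manual = 10)
  expect_equal(as.numeric(mape(one)), 10)
  three <- tibble::tibble(predicted = c(3, 5, 6), manual = c(4, 5, 5))
  expect_equal(as.numeric(mape(three)), 15)
  mixed <- tibble::tibble(predicted = c(11, 2), manual = c(10, 0))
  m <- mape(mixed)
  expect_equal(as.numeric(m), 10)              # zero-truth tray excluded
  expect_equal(attr(m, "n_trays_counted"), 1)
  expect_equal(attr(m, "zero_truth_fp"), 2)
  expect_error(mape(tibble::tibble(predicted = 1, manual = 0)), "zero")
  # order invariance
  set.seed(76)
  tbl <- tibble::tibble(predicted = sample(0:8, 10, TRUE), manual = sample(1:8, 10, TRUE))
  expect_equal(as.numeric(mape(tbl)), as.numeric(mape(tbl[sample(10), ])))
})

test_that("the aggregate report ties metrics together and derives accuracy", {
  gts <- dplyr::bind_rows(box(0, 0, 10, 10, id = "t1"),
                          box(20, 20, 30, 30, id = "t1"),
                          box(5, 5, 15, 15, id = "t2"))
  dets <- dplyr::bind_rows(box(0, 0, 10, 10, score = 0.9, id = "t1"),
                           box(5, 5, 15, 15, score = 0.8, id = "t2"))
  rep <- evaluate_detections(dets, gts, tray_ids = c("t1", "t2", "t3"))
  expect_equal(rep$precision, 1)
  expect_equal(rep$recall, 2 / 3)
  expect_equal(rep$n_trays, 3)
  expect_equal(tidy(rep)$predicted, c(1L, 1L, 0L))
  expect_equal(tidy(rep)$manual, c(2L, 1L, 0L))
  expect_equal(rep$mape_percent, 100 * (1 / 2) / 2)
  expect_equal(rep$accuracy_percent, 100 - rep$mape_percent)
  expect_equal(glance(rep)$map_coco, rep$map_coco)
  expect_error(evaluate_detections(dets, gts, tray_ids = "t1"), "t2")
})
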
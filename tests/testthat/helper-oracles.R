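# Independent brute-force oracles used to check the package implementations.
# Each one is written as directly as possible (plain loops, exhaustive
# pairwise computation) so it shares no code path with the functions under
# test.

# exhaustive pairwise k-NN: indices + distances for each point
oracle_knn <- function(X, k) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  idx <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  for (i in seq_len(n)) {
    o <- order(D[i, -i])
    others <- seq_len(n)[-i]
    idx[i, ] <- others[o[seq_len(k)]]
    dst[i, ] <- D[i, others[o[seq_len(k)]]]
  }
  list(idx = idx, dist = dst)
}

# SOR by exhaustive pairwise distances
oracle_sor_removed <- function(X, k, mult) {
  nn <- oracle_knn(X, k)
  d <- rowMeans(nn$dist)
  which(d > mean(d) + mult * stats::sd(d))
}

# interval binning of y into n equal trays, last interval closed
oracle_tray_bins <- function(y, n) {
  lo <- min(y); hi <- max(y)
  h <- (hi - lo) / n
  out <- integer(length(y))
  for (i in seq_along(y)) {
    b <- n
    for (t in seq_len(n)) {
      upper <- lo + t * h
      if (y[i] < upper) { b <- t; break }
    }
    out[i] <- b
  }
  as.integer(out)
}

# IoU by integer-pixel enumeration (boxes with integer coordinates only)
oracle_iou_pixels <- function(a, b) {
  cells <- function(bx) {
    if (bx$x_max <= bx$x_min || bx$y_max <= bx$y_min) return(character())
    g <- expand.grid(x = seq(bx$x_min, bx$x_max - 1), y = seq(bx$y_min, bx$y_max - 1))
    paste(g$x, g$y)
  }
  ca <- cells(a); cb <- cells(b)
  inter <- length(intersect(ca, cb))
  union <- length(unique(c(ca, cb)))
  inter / union
}

# plain-loop greedy matcher: detections in score order, best unmatched GT,
# strict IoU inequality, IoU ties to the lower GT index
oracle_match <- function(dets, gts, thr) {
  used <- rep(FALSE, nrow(gts))
  is_tp <- rep(FALSE, nrow(dets))
  for (i in order(-dets$score)) {
    best_iou <- -1; best_g <- 0
    for (g in seq_len(nrow(gts))) {
      if (used[g]) next
      if ("image_id" %in% names(dets) && dets$image_id[i] != gts$image_id[g]) next
      v <- canopycount::bbox_iou(dets[i, ], gts[g, ])
      if (v > best_iou) { best_iou <- v; best_g <- g }
    }
    if (best_g > 0 && best_iou > thr) { used[best_g] <- TRUE; is_tp[i] <- TRUE }
  }
  list(tp = sum(is_tp), fp = sum(!is_tp), fn = sum(!used), det_is_tp = is_tp)
}

# AP from the explicit precision-recall staircase, 101 anchors
oracle_ap <- function(dets, gts, thr) {
  if (!nrow(gts)) return(0)
  if (!nrow(dets)) return(0)
  m <- oracle_match(dets, gts, thr)
  flags <- m$det_is_tp[order(-dets$score)]
  prec <- numeric(length(flags)); rec <- numeric(length(flags))
  tp <- 0; fp <- 0
  for (i in seq_along(flags)) {
    if (flags[i]) tp <- tp + 1 else fp <- fp + 1
    prec[i] <- tp / (tp + fp)
    rec[i] <- tp / nrow(gts)
  }
  ap <- 0
  for (r in seq(0, 1, by = 0.01)) {
    p <- 0
    for (i in seq_along(flags)) if (rec[i] >= r && prec[i] > p) p <- prec[i]
    ap <- ap + p
  }
  ap / 101
}

# recursive flood fill (8-connected) component count on a logical matrix
oracle_component_count <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  count <- 0
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || seen[r0, c0]) next
    count <- count + 1
    stack <- list(c(r0, c0)); seen[r0, c0] <- TRUE
    while (length(stack)) {
      rc <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        r <- rc[1] + dr; c <- rc[2] + dc
        if (r < 1 || r > nr || c < 1 || c > nc) next
        if (mask[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          stack[[length(stack) + 1]] <- c(r, c)
        }
      }
    }
  }
  count
}

# random box tibble generator for metric tests
random_boxes <- function(n, image_id = "img", max_coord = 20, scores = TRUE) {
  if (!n) {
    out <- tibble::tibble(image_id = character(), label = character(),
                          x_min = numeric(), y_min = numeric(),
                          x_max = numeric(), y_max = numeric())
    if (scores) out$score <- numeric()
    return(out)
  }
  x0 <- sample(0:(max_coord - 2), n, replace = TRUE)
  y0 <- sample(0:(max_coord - 2), n, replace = TRUE)
  out <- tibble::tibble(
    image_id = image_id, label = "plant",
    x_min = x0, y_min = y0,
    x_max = x0 + sample(1:(max_coord %/% 2), n, replace = TRUE),
    y_max = y0 + sample(1:(max_coord %/% 2), n, replace = TRUE))
  if (scores) out$score <- round(stats::runif(n), 3)
  out
}

# dense grid cloud on a horizontal plane
plane_cloud <- function(z = 0, span = 100, spacing = 2, noise = 0) {
  g <- expand.grid(x = seq(0, span, spacing), y = seq(0, span, spacing))
  as_cloud(data.frame(x = g$x, y = g$y,
                      z = z + stats::rnorm(nrow(g), 0, noise)))
}
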
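#' Parameters for region growing segmentation
#'
#' @param k_neighbors Neighbourhood size for normals and growth (default 30).
#'   k-NN neighbourhoods are used rather than a fixed radius because laser
#'   scan density is strongly anisotropic.
#' @param angle_threshold_deg Smoothness threshold: a neighbour joins a
#'   region when the angle between its normal and the normal of the point
#'   being expanded is below this value (default 3 degrees).
#' @param curvature_threshold Points whose surface variation is below this
#'   value keep growing the region (default 1, i.e. every joined point
#'   reseeds unless tightened); surface variation is
#'   \eqn{\lambda_0/(\lambda_0+\lambda_1+\lambda_2)} of the local covariance.
#' @param min_cluster_size Regions smaller than this become unclustered
#'   (label -1; default 50).
#' @return An `rgs_params` list.
#' @export
rgs_params <- function(k_neighbors = 30, angle_threshold_deg = 3,
                       curvature_threshold = 1, min_cluster_size = 50) {
  stopifnot(k_neighbors >= 3, angle_threshold_deg > 0, angle_threshold_deg < 90,
            curvature_threshold > 0, min_cluster_size >= 1)
  structure(list(k_neighbors = as.integer(k_neighbors),
                 angle_threshold_deg = angle_threshold_deg,
                 curvature_threshold = curvature_threshold,
                 min_cluster_size = as.integer(min_cluster_size)),
            class = "rgs_params")
}

#' Estimate per-point surface normals and curvature
#'
#' For each point, the covariance of its k nearest neighbours (point
#' included) is eigen-decomposed; the normal is the eigenvector of the
#' smallest eigenvalue, flipped so its z component is non-negative (for
#' exactly vertical surfaces the sign is fixed by +y, then +x), and the
#' curvature is the surface variation
#' \eqn{\lambda_0/(\lambda_0+\lambda_1+\lambda_2)} with \eqn{\lambda_0} the
#' smallest eigenvalue (0 for a perfect plane, up to 1/3 for isotropic
#' scatter).
#'
#' @param cloud A point-cloud tibble with at least `k + 1` points.
#' @param k Neighbourhood size, at least 3.
#' @return The cloud with added columns `nx`, `ny`, `nz`, `curvature`;
#'   the neighbour index matrix is attached as attribute `knn_idx` (n x k,
#'   row i = indices of the k nearest neighbours of point i) and `k_neighbors`
#'   records k.
#' @export
estimate_normals <- function(cloud, k = 30) {
  if (k < 3) abort("k must be >= 3")
  if (nrow(cloud) < k + 1) {
    abort(sprintf("cloud has %d points; need at least k + 1 = %d",
                  nrow(cloud), k + 1))
  }
  nn <- .cc_knn(cloud_matrix(cloud), as.integer(k))
  nc <- .cc_normals(cloud_matrix(cloud), nn$idx)
  out <- cloud
  out$nx <- nc[, 1]; out$ny <- nc[, 2]; out$nz <- nc[, 3]
  out$curvature <- nc[, 4]
  attr(out, "knn_idx") <- nn$idx
  attr(out, "knn_dist") <- nn$dist
  attr(out, "k_neighbors") <- as.integer(k)
  attr(out, "source_id") <- attr(cloud, "source_id")
  out
}

#' Region growing segmentation into smooth surfaces
#'
#' Points are visited in order of ascending curvature; each still-unclustered
#' point seeds a new region which grows by breadth-first expansion over k-NN
#' neighbourhoods. A neighbour joins the region when the angle between its
#' normal and the normal of the expanding point is below
#' `angle_threshold_deg`, and itself joins the expansion front when its
#' curvature is below `curvature_threshold`. Regions smaller than
#' `min_cluster_size` are set to label -1 (unclustered). The largest cluster
#' is designated soil (ties go to the lower label id).
#'
#' @param normals A cloud augmented by [estimate_normals()] (columns
#'   `nx`, `ny`, `nz`, `curvature`). Its attached `knn_idx` neighbourhoods
#'   are reused when their k matches `params$k_neighbors`; otherwise the
#'   neighbourhoods are recomputed.
#' @param params An [rgs_params()] object.
#' @return A `soil_segmentation` object: list with `labels` (integer per
#'   point, -1 = unclustered), `soil_label`, `cluster_sizes` (named counts)
#'   and `params`.
#' @export
region_growing <- function(normals, params = rgs_params()) {
  if (!nrow(normals)) {
    return(structure(list(labels = integer(), soil_label = NA_integer_,
                          cluster_sizes = integer(), params = params),
                     class = "soil_segmentation"))
  }
  stopifnot(all(c("nx", "ny", "nz", "curvature") %in% names(normals)))
  idx <- attr(normals, "knn_idx")
  if (is.null(idx) || ncol(idx) != params$k_neighbors) {
    idx <- .cc_knn(cloud_matrix(normals), params$k_neighbors)$idx
  }
  labels <- .cc_region_growing(
    idx, cbind(normals$nx, normals$ny, normals$nz), normals$curvature,
    cos(params$angle_threshold_deg * pi / 180),
    params$curvature_threshold, params$min_cluster_size)
  labels[labels == 0L] <- -1L
  clustered <- labels[labels > 0L]
  sizes <- if (length(clustered)) table(clustered) else integer()
  sizes <- setNames(as.integer(sizes), names(sizes))
  soil <- if (length(sizes)) {
    ids <- as.integer(names(sizes))
    ids[order(-sizes, ids)][1]          # largest; tie -> lower id
  } else NA_integer_
  structure(list(labels = labels, soil_label = soil, cluster_sizes = sizes,
                 params = params),
            class = "soil_segmentation")
}

#' @export
print.soil_segmentation <- function(x, ...) {
  cat(sprintf("<soil_segmentation> %d points, %d clusters, %d unclustered; soil = cluster %s (%s points)\n",
              length(x$labels), length(x$cluster_sizes), sum(x$labels == -1L),
              x$soil_label,
              if (is.na(x$soil_label)) "0" else x$cluster_sizes[[as.character(x$soil_label)]]))
  invisible(x)
}

#' @rdname region_growing
#' @param x A `soil_segmentation` object.
#' @param ... Unused.
#' @export
tidy.soil_segmentation <- function(x, ...) {
  tibble::tibble(
    cluster = as.integer(names(x$cluster_sizes)),
    n_points = as.integer(x$cluster_sizes),
    is_soil = as.integer(names(x$cluster_sizes)) == x$soil_label
  ) |> dplyr::arrange(dplyr::desc(.data$n_points), .data$cluster)
}

#' Fit a ground plane by random sample consensus
#'
#' Repeatedly samples 3 distinct points, fits the plane through them, and
#' counts points within `distance_threshold_mm` of it; the hypothesis with
#' the most inliers wins (ties keep the earlier iteration). The winning
#' plane is then refit to all its inliers by total least squares and the
#' inlier set is recomputed once. The normal is reported with a non-negative
#' z component; the plane is `normal . p = offset`.
#'
#' @param cloud A point-cloud tibble with at least 3 non-collinear points.
#' @param distance_threshold_mm Inlier distance (default 2.5 mm).
#' @param max_iterations Number of random hypotheses (default 1000).
#' @param rng_seed Integer seed; fixed seed gives bit-identical results.
#' @return A `plane_model` object: `normal` (unit 3-vector), `offset` (mm),
#'   `inlier_indices`, `n_iterations`.
#' @export
ransac_plane <- function(cloud, distance_threshold_mm = 2.5,
                         max_iterations = 1000, rng_seed = 1) {
  n <- nrow(cloud)
  if (n < 3) abort("RANSAC needs at least 3 points")
  X <- cloud_matrix(cloud)
  best_count <- -1L; best_normal <- NULL; best_offset <- NULL
  with_local_seed(rng_seed, {
    for (it in seq_len(max_iterations)) {
      s <- sample.int(n, 3L)
      p1 <- X[s[1], ]; p2 <- X[s[2], ]; p3 <- X[s[3], ]
      nrm <- cross3(p2 - p1, p3 - p1)
      len <- sqrt(sum(nrm^2))
      if (len < 1e-12) next                     # collinear sample
      nrm <- nrm / len
      off <- sum(nrm * p1)
      cnt <- sum(abs(X %*% nrm - off) <= distance_threshold_mm)
      if (cnt > best_count) {
        best_count <- cnt; best_normal <- nrm; best_offset <- off
      }
    }
  })
  if (is.null(best_normal)) abort("degenerate geometry: all RANSAC samples collinear")
  inl <- which(abs(X %*% best_normal - best_offset) <= distance_threshold_mm)
  # total least squares refit on the consensus set, then one re-count
  fit <- fit_plane_tls(X[inl, , drop = FALSE])
  inl <- which(abs(X %*% fit$normal - fit$offset) <= distance_threshold_mm)
  structure(list(normal = fit$normal, offset = fit$offset,
                 inlier_indices = inl, n_iterations = max_iterations,
                 distance_threshold_mm = distance_threshold_mm),
            class = "plane_model")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# orthogonal-distance plane fit: centroid + smallest eigenvector of covariance
fit_plane_tls <- function(X) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  ev <- eigen(crossprod(Xc), symmetric = TRUE)
  nrm <- ev$vectors[, 3]
  if (nrm[3] < 0 || (nrm[3] == 0 && (nrm[2] < 0 || (nrm[2] == 0 && nrm[1] < 0)))) {
    nrm <- -nrm
  }
  list(normal = nrm, offset = sum(nrm * mu))
}

#' @export
print.plane_model <- function(x, ...) {
  cat(sprintf("<plane_model> normal (%.4f, %.4f, %.4f), offset %.3f mm, %d inliers (threshold %.2f mm)\n",
              x$normal[1], x$normal[2], x$normal[3], x$offset,
              length(x$inlier_indices), x$distance_threshold_mm))
  invisible(x)
}

#' @rdname ransac_plane
#' @param x A `plane_model`.
#' @param ... Unused.
#' @export
glance.plane_model <- function(x, ...) {
  tibble::tibble(nx = x$normal[1], ny = x$normal[2], nz = x$normal[3],
                 offset_mm = x$offset, n_inliers = length(x$inlier_indices),
                 distance_threshold_mm = x$distance_threshold_mm,
                 n_iterations = x$n_iterations)
}

#' Separate plant points from soil
#'
#' With `method = "rgs"` (the default, preferred because it tolerates
#' non-flat soil), the cloud is segmented into smooth surfaces and the
#' largest cluster is removed as soil; every other cluster is kept, and
#' unclustered points are kept only when they lie above the soil cluster's
#' 95th z percentile (so late-germinated small plants survive while
#' low-lying noise is dropped). With `method = "ransac"` a single ground
#' plane is fitted and its outliers are returned; on bowl-shaped soil this
#' leaves some soil behind, which is why region growing is the default.
#'
#' @param tray A frame-cleaned per-tray point-cloud tibble.
#' @param method `"rgs"` or `"ransac"`.
#' @param params For `"rgs"`, an [rgs_params()]; for `"ransac"`, a list with
#'   `distance_threshold_mm`, `max_iterations`, `rng_seed` (defaults 2.5,
#'   1000, 1).
#' @return The plant subset of `tray`. The segmentation (or plane model) is
#'   attached as attribute `soil_model`.
#' @export
extract_plants <- function(tray, method = c("rgs", "ransac"), params = NULL) {
  method <- match.arg(method)
  if (method == "rgs") {
    if (is.null(params)) params <- rgs_params()
    if (nrow(tray) < params$k_neighbors + 1) {
      # too sparse to segment: nothing to call soil
      out <- cloud_subset(tray, integer())
      attr(out, "soil_model") <- NULL
      return(out)
    }
    normals <- estimate_normals(tray, params$k_neighbors)
    seg <- region_growing(normals, params)
    if (is.na(seg$soil_label)) {
      keep <- seq_len(nrow(tray))
    } else {
      soil_z <- tray$z[seg$labels == seg$soil_label]
      z_cut <- quantile(soil_z, 0.95, names = FALSE)
      keep <- which(seg$labels != seg$soil_label &
                      (seg$labels != -1L | tray$z > z_cut))
    }
    out <- cloud_subset(tray, keep)
    attr(out, "soil_model") <- seg
  } else {
    p <- params %||% list()
    model <- ransac_plane(
      tray,
      distance_threshold_mm = p$distance_threshold_mm %||% 2.5,
      max_iterations = p$max_iterations %||% 1000,
      rng_seed = p$rng_seed %||% 1)
    out <- cloud_subset(tray, setdiff(seq_len(nrow(tray)), model$inlier_indices))
    attr(out, "soil_model") <- model
  }
  out
}

#' Naive fixed-height soil cut
#'
#' The baseline the pipeline replaces: keep every point above a single z
#' threshold. On non-flat (bowl-shaped) soil any threshold either retains
#' soil at the tray edges or discards low plant points in the middle, which
#' motivates segmentation-based soil removal.
#'
#' @param tray A per-tray point-cloud tibble.
#' @param z_cut_mm Height threshold (mm); points with `z > z_cut_mm` are kept.
#' @return The subset of `tray` above the cut.
#' @export
height_cut <- function(tray, z_cut_mm) {
  cloud_subset(tray, which(tray$z > z_cut_mm))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate expr with a temporarily-seeded RNG, restoring global RNG state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
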
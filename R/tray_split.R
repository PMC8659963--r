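#' Describe the tray layout of a scan row
#'
#' A scan row covers `n_trays` identical trays lined up along the y axis.
#' Dimensions are millimetres; `frame_width_mm` is the thickness of the tray
#' rim that is stripped before soil segmentation.
#'
#' @param n_trays Number of trays in the scan row (default 12).
#' @param tray_length_mm Tray extent along the lineup (y) axis, default 640.
#' @param tray_width_mm Tray extent along x, default 400.
#' @param tray_height_mm Tray depth, default 425.
#' @param frame_width_mm Rim thickness removed by [remove_frame()], default 20.
#' @return A `tray_layout` list.
#' @examples
#' tray_layout(n_trays = 12)
#' @export
tray_layout <- function(n_trays = 12, tray_length_mm = 640,
                        tray_width_mm = 400, tray_height_mm = 425,
                        frame_width_mm = 20) {
  if (n_trays < 1) abort("n_trays must be >= 1")
  dims <- c(tray_length_mm, tray_width_mm, tray_height_mm, frame_width_mm)
  if (any(dims <= 0)) abort("tray dimensions must be positive")
  if (frame_width_mm >= min(tray_length_mm, tray_width_mm) / 2) {
    abort("frame_width_mm must be smaller than half the smallest tray side")
  }
  structure(
    list(n_trays = as.integer(n_trays), tray_length_mm = tray_length_mm,
         tray_width_mm = tray_width_mm, tray_height_mm = tray_height_mm,
         frame_width_mm = frame_width_mm, lineup_axis = "y"),
    class = "tray_layout")
}

#' @export
print.tray_layout <- function(x, ...) {
  cat(sprintf("<tray_layout> %d trays of %g x %g x %g mm, frame %g mm, lined along y\n",
              x$n_trays, x$tray_length_mm, x$tray_width_mm, x$tray_height_mm,
              x$frame_width_mm))
  invisible(x)
}

#' Assign each point of a scan row to a tray
#'
#' The observed y extent `[y_min, y_max]` of the cloud is divided into
#' `n_trays` equal intervals, half-open `[lo, hi)` except the last which is
#' closed, so every point falls in exactly one tray; a point exactly on an
#' interior boundary goes to the higher-index tray.
#'
#' @param cloud A point-cloud tibble.
#' @param layout A [tray_layout()].
#' @return The cloud with an added integer `tray` column (1-based).
#' @export
assign_trays <- function(cloud, layout) {
  if (!nrow(cloud)) abort("cannot split an empty cloud")
  n <- layout$n_trays
  if (n < 1) abort("n_trays must be >= 1")
  rng <- range(cloud$y)
  h <- (rng[2] - rng[1]) / n
  idx <- if (h > 0) pmin(floor((cloud$y - rng[1]) / h), n - 1) else 0
  cloud$tray <- as.integer(idx + 1L)
  cloud
}

#' Split a scan row into per-tray clouds
#'
#' @inheritParams assign_trays
#' @return A list of `n_trays` point-cloud tibbles, in tray order (ascending
#'   y). Together they partition the input; empty trays give empty clouds.
#' @seealso [assign_trays()] for the tibble form.
#' @export
split_trays <- function(cloud, layout) {
  assigned <- assign_trays(cloud, layout)
  lapply(seq_len(layout$n_trays), function(i) {
    cloud_subset(cloud, which(assigned$tray == i))
  })
}

#' Strip the tray frame (rim) from a per-tray cloud
#'
#' Removes every point lying within `frame_width_mm` of the boundary of the
#' tray's x-y bounding rectangle; only soil and plants remain. The test is
#' purely planimetric (no z). The returned cloud carries a `frame_removed`
#' attribute and re-applying the function to it is a no-op, so the rim is
#' never peeled twice.
#'
#' @param tray A per-tray point-cloud tibble (from [split_trays()]).
#' @param layout A [tray_layout()]; only `frame_width_mm` is used.
#' @return The subset of `tray` outside the rim margin (possibly empty).
#' @export
remove_frame <- function(tray, layout) {
  if (!nrow(tray) || isTRUE(attr(tray, "frame_removed"))) return(tray)
  w <- layout$frame_width_mm
  xr <- range(tray$x); yr <- range(tray$y)
  margin <- pmin(tray$x - xr[1], xr[2] - tray$x,
                 tray$y - yr[1], yr[2] - tray$y)
  out <- cloud_subset(tray, which(margin >= w))
  attr(out, "frame_removed") <- TRUE
  out
}
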
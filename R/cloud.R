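#' Construct or validate a point-cloud tibble
#'
#' A point cloud is a tibble with numeric columns `x`, `y`, `z` in
#' millimetres and an optional `intensity` column (unitless laser-return
#' strength, carried through I/O but never used for colouring). The scan file
#' a cloud came from is recorded in the `source_id` attribute.
#'
#' @param xyz A data frame (or matrix) whose first three columns are x, y, z
#'   coordinates in mm; an optional fourth column is taken as intensity.
#' @param intensity Optional numeric vector of per-point intensities.
#' @param source_id Text identifier of the originating scan, default `""`.
#' @return A tibble of class `cc_cloud` with columns `x`, `y`, `z` and
#'   optionally `intensity`.
#' @examples
#' cloud <- as_cloud(data.frame(x = 0:2, y = 0, z = c(1, 2, 3)))
#' n_points(cloud)
#' @export
as_cloud <- function(xyz, intensity = NULL, source_id = "") {
  if (is.matrix(xyz)) xyz <- as.data.frame(xyz)
  stopifnot(is.data.frame(xyz), ncol(xyz) >= 3)
  cloud <- tibble::tibble(
    x = as.double(xyz[[1]]),
    y = as.double(xyz[[2]]),
    z = as.double(xyz[[3]])
  )
  if (is.null(intensity) && ncol(xyz) >= 4) intensity <- as.double(xyz[[4]])
  if (!is.null(intensity)) {
    if (length(intensity) != nrow(cloud)) {
      abort("intensity length must equal the number of points")
    }
    cloud$intensity <- as.double(intensity)
  }
  bad <- !stats::complete.cases(cloud[c("x", "y", "z")]) |
    !is.finite(cloud$x) | !is.finite(cloud$y) | !is.finite(cloud$z)
  if (any(bad)) {
    abort(sprintf("cloud contains %d non-finite coordinates", sum(bad)))
  }
  attr(cloud, "source_id") <- source_id
  class(cloud) <- c("cc_cloud", class(cloud))
  cloud
}

#' Number of points in a cloud
#' @param cloud A point-cloud tibble.
#' @return Integer point count.
#' @export
n_points <- function(cloud) nrow(cloud)

# internal: coordinates as n x 3 matrix for the C++ kernels
cloud_matrix <- function(cloud) {
  cbind(cloud$x, cloud$y, cloud$z)
}

# internal: keep cc_cloud class/attributes after a row subset
cloud_subset <- function(cloud, keep) {
  out <- cloud[keep, , drop = FALSE]
  attr(out, "source_id") <- attr(cloud, "source_id")
  if (!inherits(out, "cc_cloud")) class(out) <- c("cc_cloud", class(out))
  out
}
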
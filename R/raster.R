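#' Statistical outlier removal
#'
#' For each point the mean distance to its `k_neighbors` nearest neighbours
#' is computed; points whose mean distance exceeds the global
#' mean + `std_multiplier` * sd of those mean distances are removed. Point
#' order is preserved. Clouds with too few points are returned unchanged
#' with a warning.
#'
#' @param cloud A point-cloud tibble.
#' @param k_neighbors Neighbourhood size (default 16).
#' @param std_multiplier Cut-off in standard deviations (default 2). Larger
#'   multipliers never remove more points.
#' @return The filtered cloud (subset of the input, original order).
#' @export
sor_filter <- function(cloud, k_neighbors = 16, std_multiplier = 2) {
  stopifnot(k_neighbors >= 1, std_multiplier > 0)
  if (nrow(cloud) <= k_neighbors) {
    warn(sprintf("sor_filter: cloud has %d points (<= k = %d); returning unchanged",
                 nrow(cloud), k_neighbors))
    return(cloud)
  }
  nn <- .cc_knn(cloud_matrix(cloud), as.integer(k_neighbors))
  d <- rowMeans(nn$dist)
  cutoff <- mean(d) + std_multiplier * sd(d)
  cloud_subset(cloud, which(d <= cutoff))
}

#' Map a normalised height to an RGB colour
#'
#' Piecewise-linear blue-green-red colormap: height 0 is pure blue
#' (0, 0, 255), 0.5 pure green (0, 255, 0) and 1 pure red (255, 0, 0), with
#' linear interpolation inside each half. The output never equals the
#' reserved black background. Values outside \[0, 1\] are clamped with a
#' warning.
#'
#' @param h_norm Numeric vector of normalised heights in \[0, 1\].
#' @return An n x 3 integer matrix of RGB values in \[0, 255\].
#' @examples
#' height_to_color(c(0, 0.5, 1))
#' @export
height_to_color <- function(h_norm) {
  if (any(h_norm < 0 | h_norm > 1, na.rm = TRUE)) {
    warn("height_to_color: values outside [0, 1] clamped")
    h_norm <- pmin(pmax(h_norm, 0), 1)
  }
  lo <- h_norm <= 0.5
  r <- ifelse(lo, 0, round(255 * (2 * h_norm - 1)))
  g <- ifelse(lo, round(255 * 2 * h_norm), round(255 * (2 - 2 * h_norm)))
  b <- ifelse(lo, round(255 * (1 - 2 * h_norm)), 0)
  m <- cbind(r = r, g = g, b = b)
  storage.mode(m) <- "integer"
  m
}

#' Rasterize a plant cloud to a height-coloured 2D image
#'
#' Points are projected onto the x-y plane and binned into square pixels of
#' side `pixel_size_mm`; each occupied pixel takes the maximum z of its
#' points (canopy-surface view), normalised per cloud over
#' `[min(z), max(z)]` and coloured with [height_to_color()]. Empty pixels
#' get the reserved black background. Row 1 of the pixel array corresponds
#' to the minimal y (mathematical orientation); [write_raster_png()] flips
#' to the top-left image convention on export.
#'
#' @param cloud The plant point-cloud tibble (may be empty).
#' @param pixel_size_mm Pixel side in mm (default 0.8, the scanner's x-y
#'   resolution, i.e. roughly one point per pixel).
#' @param extent Tray rectangle `c(x_min, x_max, y_min, y_max)` in mm; by
#'   default the cloud's own bounding rectangle. Points outside it are
#'   ignored.
#' @return A `raster_image` object: list with `pixels` (H x W x 3 integer
#'   array), `pixel_size_mm`, `origin_xy_mm` (world coordinates of the
#'   lower-left corner of pixel (1,1)), `background_rgb` and `z_range_mm`.
#' @export
rasterize <- function(cloud, pixel_size_mm = 0.8, extent = NULL) {
  stopifnot(pixel_size_mm > 0)
  if (is.null(extent)) {
    if (!nrow(cloud)) abort("empty cloud needs an explicit extent")
    extent <- c(range(cloud$x), range(cloud$y))
  }
  stopifnot(length(extent) == 4, extent[2] >= extent[1], extent[4] >= extent[3])
  s <- pixel_size_mm
  W <- max(1L, as.integer(ceiling((extent[2] - extent[1]) / s)))
  H <- max(1L, as.integer(ceiling((extent[4] - extent[3]) / s)))
  px <- array(0L, dim = c(H, W, 3))
  zr <- c(NA_real_, NA_real_)
  if (nrow(cloud)) {
    col <- floor((cloud$x - extent[1]) / s)
    row <- floor((cloud$y - extent[3]) / s)
    # points exactly on the max boundary fall into the last pixel
    col[cloud$x == extent[2]] <- W - 1
    row[cloud$y == extent[4]] <- H - 1
    keep <- col >= 0 & col < W & row >= 0 & row < H
    if (any(keep)) {
      col <- col[keep]; row <- row[keep]; z <- cloud$z[keep]
      cell <- row * W + col + 1
      zr <- range(z)
      hmax <- rep(-Inf, H * W)
      o <- order(z)                      # later assignment wins -> max z
      hmax[cell[o]] <- z[o]
      occ <- which(is.finite(hmax))
      h <- if (zr[2] > zr[1]) (hmax[occ] - zr[1]) / (zr[2] - zr[1]) else rep(0, length(occ))
      rgb <- height_to_color(h)
      r0 <- (occ - 1) %/% W              # linear cell -> (row, col)
      c0 <- (occ - 1) %% W
      for (ch in 1:3) px[cbind(r0 + 1, c0 + 1, ch)] <- rgb[, ch]
    }
  }
  structure(list(pixels = px, pixel_size_mm = s,
                 origin_xy_mm = c(extent[1], extent[3]),
                 background_rgb = c(0L, 0L, 0L), z_range_mm = zr),
            class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<raster_image> %d x %d px (%.2f mm/px), origin (%.1f, %.1f) mm, %d plant pixels\n",
              d[2], d[1], x$pixel_size_mm, x$origin_xy_mm[1], x$origin_xy_mm[2],
              sum(plant_mask(x))))
  invisible(x)
}

# logical H x W mask of non-background pixels
plant_mask <- function(image) {
  bg <- image$background_rgb
  image$pixels[, , 1] != bg[1] | image$pixels[, , 2] != bg[2] |
    image$pixels[, , 3] != bg[3]
}

#' Image width/height in pixels
#' @param image A `raster_image`.
#' @return Named integer vector `c(width, height)`.
#' @export
raster_size <- function(image) {
  d <- dim(image$pixels)
  c(width = d[2], height = d[1])
}

#' Long-format pixel table of a raster image
#' @param x A `raster_image`.
#' @param ... Unused.
#' @return Tibble with `col`, `row` (1-based, row 1 = minimal y), `r`, `g`,
#'   `b` and `is_plant` columns.
#' @export
tidy.raster_image <- function(x, ...) {
  d <- dim(x$pixels)
  tibble::tibble(
    row = rep(seq_len(d[1]), d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    r = as.integer(x$pixels[, , 1]),
    g = as.integer(x$pixels[, , 2]),
    b = as.integer(x$pixels[, , 3]),
    is_plant = as.vector(plant_mask(x))
  )
}

#' Export a raster image as 8-bit RGB PNG with a geometry sidecar
#'
#' Rows are flipped so the PNG has its usual top-left origin; a JSON sidecar
#' (`<path>.json`) stores `pixel_size_mm` and `origin_xy_mm` so pixel
#' coordinates can be mapped back to world millimetres.
#'
#' @param image A `raster_image`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_raster_png <- function(image, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    abort("the 'png' package is required to write PNG files")
  }
  a <- image$pixels[rev(seq_len(dim(image$pixels)[1])), , , drop = FALSE] / 255
  png::writePNG(a, path)
  jsonlite::write_json(
    list(pixel_size_mm = image$pixel_size_mm,
         origin_xy_mm = image$origin_xy_mm,
         width = dim(image$pixels)[2], height = dim(image$pixels)[1]),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Plot a raster image, optionally with detection boxes
#'
#' @param object A `raster_image`.
#' @param boxes Optional detection/annotation tibble drawn as open
#'   rectangles.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.raster_image <- function(object, boxes = NULL, ...) {
  df <- tidy(object)
  df$fill <- grDevices::rgb(df$r, df$g, df$b, maxColorValue = 255)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col - 0.5, y = .data$row - 0.5)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
  if (!is.null(boxes) && nrow(boxes)) {
    p <- p + ggplot2::geom_rect(
      data = as.data.frame(boxes),
      ggplot2::aes(xmin = .data$x_min, xmax = .data$x_max,
                   ymin = .data$y_min, ymax = .data$y_max),
      inherit.aes = FALSE, colour = "white", fill = NA, linewidth = 0.4)
  }
  p
}
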
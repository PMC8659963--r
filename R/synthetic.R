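#' Specification of a synthetic multi-tray scan
#'
#' Describes a scan row the way the phenotyping platform produces one:
#' trays lined along y, each holding bowl-shaped soil (less soil in the
#' middle of the tray than at the sides), a raised rim, 0-8 plants modelled
#' as a vertical stem plus leaf disks, and a sparse fraction of clutter
#' points (scanner noise, barcode reflections). Every draw is taken from a
#' single RNG stream seeded once, in a fixed documented order (per tray:
#' soil, rim, plant count, plant placement, plant geometry, clutter), so a
#' spec plus seed reproduces the scene byte for byte.
#'
#' @param layout A [tray_layout()].
#' @param plants_per_tray Inclusive integer range of plants per tray,
#'   default `c(0, 8)`.
#' @param soil_base_z_mm Soil level at the tray sides (default 50).
#' @param soil_bowl_depth_mm How much lower the soil is at the tray centre
#'   (default 15; deep enough that no single fixed-height cut separates
#'   plants from soil).
#' @param soil_noise_sd_mm Gaussian roughness of the soil surface (default 1).
#' @param plant_height_range_mm Range of plant heights above the soil base
#'   (default `c(60, 160)`).
#' @param leaf_count_range Leaves per plant (default `c(3, 6)`).
#' @param leaf_radius_range_mm Leaf disk radii (default `c(15, 35)`).
#' @param clutter_fraction Sparse outlier points as a fraction of the tray's
#'   structured points (default 0.01).
#' @param point_spacing_mm Sampling grid spacing (default 3; a coarser grid
#'   than the scanner's 0.8 mm so that multi-tray scenes stay light while
#'   keeping >1000 points per plant).
#' @param rim_height_mm Height of the tray rim above the soil base
#'   (default 40).
#' @param rng_seed Integer seed (default 1).
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(layout = tray_layout(),
                       plants_per_tray = c(0, 8),
                       soil_base_z_mm = 50,
                       soil_bowl_depth_mm = 15,
                       soil_noise_sd_mm = 1,
                       plant_height_range_mm = c(60, 160),
                       leaf_count_range = c(3, 6),
                       leaf_radius_range_mm = c(15, 35),
                       clutter_fraction = 0.01,
                       point_spacing_mm = 3,
                       rim_height_mm = 40,
                       rng_seed = 1) {
  stopifnot(length(plants_per_tray) == 2, plants_per_tray[1] <= plants_per_tray[2],
            plants_per_tray[1] >= 0,
            plant_height_range_mm[1] <= plant_height_range_mm[2],
            leaf_count_range[1] <= leaf_count_range[2], leaf_count_range[1] >= 1,
            leaf_radius_range_mm[1] <= leaf_radius_range_mm[2],
            clutter_fraction >= 0, clutter_fraction < 1,
            point_spacing_mm > 0, soil_noise_sd_mm >= 0, soil_bowl_depth_mm >= 0)
  structure(list(layout = layout, plants_per_tray = as.integer(plants_per_tray),
                 soil_base_z_mm = soil_base_z_mm,
                 soil_bowl_depth_mm = soil_bowl_depth_mm,
                 soil_noise_sd_mm = soil_noise_sd_mm,
                 plant_height_range_mm = plant_height_range_mm,
                 leaf_count_range = as.integer(leaf_count_range),
                 leaf_radius_range_mm = leaf_radius_range_mm,
                 clutter_fraction = clutter_fraction,
                 point_spacing_mm = point_spacing_mm,
                 rim_height_mm = rim_height_mm,
                 rng_seed = as.integer(rng_seed)),
            class = "scene_spec")
}

# jittered rectangular grid of (x, y) points
jitter_grid <- function(x0, x1, y0, y1, spacing, jitter_sd) {
  xs <- seq(x0 + spacing / 2, x1, by = spacing)
  ys <- seq(y0 + spacing / 2, y1, by = spacing)
  g <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  n <- nrow(g)
  g$x <- pmin(pmax(g$x + stats::rnorm(n, 0, jitter_sd), x0), x1)
  g$y <- pmin(pmax(g$y + stats::rnorm(n, 0, jitter_sd), y0), y1)
  g
}

#' Generate a synthetic scan row with exact ground truth
#'
#' @param spec A [scene_spec()].
#' @return A list with `cloud` (point-cloud tibble) and `truth`
#'   (`scene_truth`: per-tray counts, per-plant world-mm footprint boxes,
#'   and the role of every point). Point roles (`soil`, `rim`, `plant`,
#'   `clutter`) partition the cloud.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  lay <- spec$layout
  s <- spec$point_spacing_mm
  r_max <- spec$leaf_radius_range_mm[2]
  with_local_seed(spec$rng_seed, {
    parts <- vector("list", lay$n_trays)
    plant_rows <- list()
    for (t in seq_len(lay$n_trays)) {
      y_off <- (t - 1) * lay$tray_length_mm
      fw <- lay$frame_width_mm
      W <- lay$tray_width_mm; L <- lay$tray_length_mm

      # --- soil: jittered grid, bowl-shaped (lower in the middle) + noise
      g <- jitter_grid(fw, W - fw, fw, L - fw, s, s / 4)
      u <- (g$x - fw) / (W - 2 * fw)
      v <- (g$y - fw) / (L - 2 * fw)
      bowl <- sin(pi * pmin(pmax(u, 0), 1)) * sin(pi * pmin(pmax(v, 0), 1))
      soil <- tibble::tibble(
        x = g$x, y = g$y + y_off,
        z = spec$soil_base_z_mm - spec$soil_bowl_depth_mm * bowl +
          stats::rnorm(nrow(g), 0, spec$soil_noise_sd_mm),
        role = "soil", plant = NA_integer_)

      # --- rim: flat band of width fw around the tray border
      rim_g <- jitter_grid(0, W, 0, L, s, s / 4)
      on_rim <- rim_g$x < fw | rim_g$x > W - fw | rim_g$y < fw | rim_g$y > L - fw
      rim_g <- rim_g[on_rim, , drop = FALSE]
      rim <- tibble::tibble(
        x = rim_g$x, y = rim_g$y + y_off,
        z = spec$soil_base_z_mm + spec$rim_height_mm +
          stats::rnorm(nrow(rim_g), 0, 0.3),
        role = "rim", plant = NA_integer_)

      # --- plants
      n_p <- if (spec$plants_per_tray[1] == spec$plants_per_tray[2]) {
        spec$plants_per_tray[1]
      } else {
        sample(spec$plants_per_tray[1]:spec$plants_per_tray[2], 1)
      }
      margin <- fw + r_max + 5
      centers <- place_centers(n_p, margin, W - margin, margin, L - margin,
                               2 * r_max)
      plants <- vector("list", n_p)
      for (p in seq_len(n_p)) {
        # plants grow from the local soil surface, so a short plant in the
        # middle of the bowl can sit below the soil level at the tray sides
        uc <- (centers[p, 1] - fw) / (W - 2 * fw)
        vc <- (centers[p, 2] - fw) / (L - 2 * fw)
        z_anchor <- spec$soil_base_z_mm -
          spec$soil_bowl_depth_mm * sin(pi * uc) * sin(pi * vc)
        pl <- sample_plant(spec, centers[p, 1], centers[p, 2] + y_off, z_anchor)
        pl$role <- "plant"; pl$plant <- p
        plants[[p]] <- pl
      }
      plants <- if (n_p) dplyr::bind_rows(plants) else soil[0, ]

      # --- clutter: uniform in the tray volume
      n_struct <- nrow(soil) + nrow(rim) + nrow(plants)
      n_cl <- round(spec$clutter_fraction * n_struct)
      clutter <- tibble::tibble(
        x = stats::runif(n_cl, 0, W),
        y = stats::runif(n_cl, 0, L) + y_off,
        z = stats::runif(n_cl, spec$soil_base_z_mm - spec$soil_bowl_depth_mm,
                         spec$soil_base_z_mm + spec$plant_height_range_mm[2] + 20),
        role = "clutter", plant = NA_integer_)

      tray_pts <- dplyr::bind_rows(soil, rim, plants, clutter)
      tray_pts$tray <- t
      parts[[t]] <- tray_pts
      if (n_p) {
        pp <- plants |>
          dplyr::group_by(.data$plant) |>
          dplyr::summarise(x_min = min(.data$x), x_max = max(.data$x),
                           y_min = min(.data$y), y_max = max(.data$y),
                           .groups = "drop")
        pp$center_x <- centers[pp$plant, 1]
        pp$center_y <- centers[pp$plant, 2] + y_off
        pp$tray <- t
        plant_rows[[length(plant_rows) + 1]] <- pp
      }
    }
    all_pts <- dplyr::bind_rows(parts)
    cloud <- as_cloud(all_pts[c("x", "y", "z")], source_id = "synthetic")
    plants_tbl <- if (length(plant_rows)) dplyr::bind_rows(plant_rows) else NULL
    truth <- structure(list(
      per_tray = tibble::tibble(
        tray = seq_len(lay$n_trays),
        image_id = tray_image_id(seq_len(lay$n_trays)),
        n_plants = vapply(seq_len(lay$n_trays), function(t) {
          if (is.null(plants_tbl)) 0L else sum(plants_tbl$tray == t)
        }, integer(1))),
      plants = if (length(plant_rows)) {
        dplyr::bind_rows(plant_rows)[c("tray", "plant", "center_x", "center_y",
                                       "x_min", "y_min", "x_max", "y_max")]
      } else {
        tibble::tibble(tray = integer(), plant = integer(),
                       center_x = numeric(), center_y = numeric(),
                       x_min = numeric(), y_min = numeric(),
                       x_max = numeric(), y_max = numeric())
      },
      points = tibble::tibble(tray = all_pts$tray, role = all_pts$role,
                              plant = all_pts$plant),
      spec = spec), class = "scene_truth")
    list(cloud = cloud, truth = truth)
  })
}

# rejection-sample n centres with pairwise distance >= min_dist
place_centers <- function(n, x0, x1, y0, y1, min_dist, max_tries = 200) {
  if (!n) return(matrix(numeric(), 0, 2))
  if (x1 <= x0 || y1 <= y0) abort("tray too small for the requested plants")
  out <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- c(stats::runif(1, x0, x1), stats::runif(1, y0, y1))
      if (i == 1 || all(sqrt(rowSums(sweep(out[seq_len(i - 1), , drop = FALSE],
                                           2, cand)^2)) >= min_dist)) {
        out[i, ] <- cand; placed <- TRUE; break
      }
    }
    if (!placed) {
      abort(sprintf("could not place %d non-overlapping plants; request fewer plants", n))
    }
  }
  out
}

# one plant: vertical stem + leaf disks anchored at the local soil surface
sample_plant <- function(spec, cx, cy, z_anchor) {
  s <- spec$point_spacing_mm
  base <- z_anchor
  h <- stats::runif(1, spec$plant_height_range_mm[1], spec$plant_height_range_mm[2])
  n_leaves <- if (spec$leaf_count_range[1] == spec$leaf_count_range[2]) {
    spec$leaf_count_range[1]
  } else {
    sample(spec$leaf_count_range[1]:spec$leaf_count_range[2], 1)
  }
  stem_z <- seq(base - 5, base + h, by = s / 2)
  stem <- tibble::tibble(
    x = cx + stats::rnorm(length(stem_z), 0, 0.5),
    y = cy + stats::rnorm(length(stem_z), 0, 0.5),
    z = stem_z)
  leaves <- lapply(seq_len(n_leaves), function(l) {
    r <- stats::runif(1, spec$leaf_radius_range_mm[1], spec$leaf_radius_range_mm[2])
    hz <- base + stats::runif(1, 0.35, 1) * h
    off <- stats::runif(1, 0, 0.35 * r)
    ang <- stats::runif(1, 0, 2 * pi)
    lcx <- cx + off * cos(ang); lcy <- cy + off * sin(ang)
    ecc <- stats::runif(1, 0.6, 1)
    rot <- stats::runif(1, 0, pi)
    g <- jitter_grid(lcx - r, lcx + r, lcy - r, lcy + r, s, s / 4)
    dx <- g$x - lcx; dy <- g$y - lcy
    a <- dx * cos(rot) + dy * sin(rot)
    b <- -dx * sin(rot) + dy * cos(rot)
    inside <- (a / r)^2 + (b / (r * ecc))^2 <= 1
    g <- g[inside, , drop = FALSE]
    tibble::tibble(x = g$x, y = g$y,
                   z = hz + stats::rnorm(nrow(g), 0, 0.3))
  })
  dplyr::bind_rows(c(list(stem), leaves))
}

#' Tray image identifiers
#' @param tray Integer tray indices.
#' @return Character ids like `"tray_03"`.
#' @export
tray_image_id <- function(tray) sprintf("tray_%02d", tray)

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("<scene_truth> %d trays, %d plants, %d points\n",
              nrow(x$per_tray), nrow(x$plants), nrow(x$points)))
  invisible(x)
}

#' Per-tray plant counts of a scene truth
#' @param x A `scene_truth`.
#' @param ... Unused.
#' @return The `per_tray` tibble (`tray`, `image_id`, `n_plants`).
#' @export
tidy.scene_truth <- function(x, ...) x$per_tray

#' Convert ground-truth plant footprints to pixel annotations
#'
#' World-mm footprint boxes are mapped into each tray raster's pixel frame
#' (half-open boxes: `floor` on the low edge, `ceiling` on the high edge),
#' clipped to the image bounds; boxes with no area left after clipping are
#' dropped with a warning.
#'
#' @param truth A `scene_truth` from [generate_scene()].
#' @param geometries A named list (names = tray `image_id`s) of raster
#'   geometries — each either a `raster_image` or a list with
#'   `pixel_size_mm`, `origin_xy_mm`, `width`, `height`.
#' @return An annotation tibble (`cc_boxes`) over all trays with geometry,
#'   labels `"plant"`.
#' @export
truth_to_annotations <- function(truth, geometries) {
  rows <- list()
  dropped <- 0L
  for (t in seq_len(nrow(truth$per_tray))) {
    id <- truth$per_tray$image_id[t]
    geo <- geometries[[id]]
    if (is.null(geo)) next
    if (inherits(geo, "raster_image")) {
      geo <- list(pixel_size_mm = geo$pixel_size_mm,
                  origin_xy_mm = geo$origin_xy_mm,
                  width = dim(geo$pixels)[2], height = dim(geo$pixels)[1])
    }
    pl <- truth$plants[truth$plants$tray == truth$per_tray$tray[t], , drop = FALSE]
    if (!nrow(pl)) next
    sp <- geo$pixel_size_mm; ox <- geo$origin_xy_mm[1]; oy <- geo$origin_xy_mm[2]
    b <- tibble::tibble(
      image_id = id, label = "plant",
      x_min = pmax(0, floor((pl$x_min - ox) / sp)),
      y_min = pmax(0, floor((pl$y_min - oy) / sp)),
      x_max = pmin(geo$width, ceiling((pl$x_max - ox) / sp)),
      y_max = pmin(geo$height, ceiling((pl$y_max - oy) / sp)))
    ok <- b$x_max > b$x_min & b$y_max > b$y_min
    dropped <- dropped + sum(!ok)
    rows[[length(rows) + 1]] <- b[ok, , drop = FALSE]
  }
  if (dropped) warn(sprintf("%d ground-truth boxes degenerate after clipping; dropped", dropped))
  out <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(image_id = character(), label = character(),
                   x_min = numeric(), y_min = numeric(),
                   x_max = numeric(), y_max = numeric())
  }
  as_boxes(out)
}
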
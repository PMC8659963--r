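small_layout <- tray_layout(n_trays = 2, tray_length_mm = 320,
                            tray_width_mm = 240, frame_width_mm = 15)

test_that("an all-empty scene has no plant points and zero counts", {
  sc <- generate_scene(scene_spec(layout = small_layout,
                                  plants_per_tray = c(0, 0), rng_seed = 81))
  expect_equal(sum(tidy(sc$truth)$n_plants), 0)
  expect_equal(nrow(sc$truth$plants), 0)
  expect_false(any(sc$truth$points$role == "plant"))
})

test_that("the same spec and seed reproduce the scene byte for byte", {
  spec <- scene_spec(layout = small_layout, plants_per_tray = c(0, 4),
                     rng_seed = 82)
  a <- generate_scene(spec)
  b <- generate_scene(spec)
  expect_identical(a$cloud, b$cloud)
  expect_identical(a$truth$plants, b$truth$plants)
  expect_identical(a$truth$points, b$truth$points)
  c <- generate_scene(scene_spec(layout = small_layout, plants_per_tray = c(0, 4),
                                 rng_seed = 83))
  expect_false(identical(a$cloud, c$cloud))
})

test_that("roles partition the cloud and counts match the index partition", {
  sc <- generate_scene(scene_spec(layout = small_layout,
                                  plants_per_tray = c(1, 3), rng_seed = 84))
  expect_equal(nrow(sc$truth$points), nrow(sc$cloud))
  expect_true(all(sc$truth$points$role %in% c("soil", "rim", "plant", "clutter")))
  expect_equal(sum(!is.na(sc$truth$points$plant)),
               sum(sc$truth$points$role == "plant"))
  # per-tray plant ids match the footprint table
  for (t in 1:2) {
    ids <- unique(stats::na.omit(sc$truth$points$plant[sc$truth$points$tray == t]))
    expect_setequal(ids, sc$truth$plants$plant[sc$truth$plants$tray == t])
  }
})

test_that("plant placement respects counts in range and minimum separation", {
  spec <- scene_spec(plants_per_tray = c(0, 8), rng_seed = 1)
  sc <- generate_scene(spec)
  counts <- tidy(sc$truth)$n_plants
  expect_length(counts, 12)
  expect_true(all(counts >= 0 & counts <= 8))
  min_sep <- 2 * spec$leaf_radius_range_mm[2]
  for (t in unique(sc$truth$plants$tray)) {
    p <- sc$truth$plants[sc$truth$plants$tray == t, ]
    if (nrow(p) < 2) next
    d <- as.matrix(stats::dist(cbind(p$center_x, p$center_y)))
    expect_true(all(d[upper.tri(d)] >= min_sep))
  }
  # footprint boxes stay inside their tray's extent
  lay <- spec$layout
  expect_true(all(sc$truth$plants$x_min >= 0 &
                    sc$truth$plants$x_max <= lay$tray_width_mm))
})

test_that("an over-packed tray fails with a clear placement error", {
  tiny <- tray_layout(n_trays = 1, tray_length_mm = 200, tray_width_mm = 200,
                      frame_width_mm = 10)
  expect_error(
    generate_scene(scene_spec(layout = tiny, plants_per_tray = c(8, 8),
                              rng_seed = 85)),
    "fewer plants")
})

test_that("the soil is bowl-shaped: centre lower than the sides", {
  spec <- scene_spec(layout = tray_layout(n_trays = 1), plants_per_tray = c(0, 0),
                     soil_bowl_depth_mm = 15, rng_seed = 86)
  sc <- generate_scene(spec)
  soil <- sc$cloud[sc$truth$points$role == "soil", ]
  lay <- spec$layout
  r <- sqrt(((soil$x - lay$tray_width_mm / 2) / lay$tray_width_mm)^2 +
              ((soil$y - lay$tray_length_mm / 2) / lay$tray_length_mm)^2)
  centre <- soil$z[r < 0.1]
  edges <- soil$z[r > 0.45]
  expect_gte(mean(edges) - mean(centre), 0.8 * spec$soil_bowl_depth_mm)
})

test_that("truth footprints convert to pixel boxes that invert to world mm", {
  spec <- scene_spec(layout = small_layout, plants_per_tray = c(2, 2),
                     point_spacing_mm = 3, rng_seed = 87)
  sc <- generate_scene(spec)
  lay <- spec$layout
  trays <- split_trays(sc$cloud, lay)
  geoms <- list()
  for (t in 1:2) {
    clean <- remove_frame(trays[[t]], lay)
    geoms[[tray_image_id(t)]] <- rasterize(clean, 3, c(range(clean$x), range(clean$y)))
  }
  ann <- truth_to_annotations(sc$truth, geoms)
  expect_equal(nrow(ann), 4)
  expect_true(all(ann$label == "plant"))
  # pixel-box centre back-projected to world is within a pixel of the truth
  for (i in seq_len(nrow(ann))) {
    t <- match(ann$image_id[i], tray_image_id(1:2))
    g <- geoms[[ann$image_id[i]]]
    wx <- g$origin_xy_mm[1] + (ann$x_min[i] + ann$x_max[i]) / 2 * g$pixel_size_mm
    wy <- g$origin_xy_mm[2] + (ann$y_min[i] + ann$y_max[i]) / 2 * g$pixel_size_mm
    pl <- sc$truth$plants[sc$truth$plants$tray == t, ]
    wcx <- (pl$x_min + pl$x_max) / 2; wcy <- (pl$y_min + pl$y_max) / 2
    expect_lt(min(sqrt((wcx - wx)^2 + (wcy - wy)^2)), g$pixel_size_mm)
  }
  expect_equal(nrow(truth_to_annotations(
    generate_scene(scene_spec(layout = small_layout, plants_per_tray = c(0, 0),
                              rng_seed = 88))$truth, geoms)), 0)
})
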
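disc_ndvi <- function(n, centres, radius_px, bg = 0.1, fg = 0.8, gsd = 0.01) {
  v <- matrix(bg, n, n)
  for (ct in centres) {
    d2 <- outer((seq_len(n) - ct[1])^2, (seq_len(n) - ct[2])^2, "+")
    v[d2 <= radius_px^2] <- fg
  }
  raster_grid(v, gsd = gsd)
}

test_that("segmentation finds the right component count", {
  # all below threshold -> zero components with a warning
  low <- raster_grid(matrix(0.1, 20, 20), gsd = 0.01)
  expect_warning(lab0 <- segment_plants(low), "empty")
  expect_identical(attr(lab0, "n_components"), 0L)
  # one disc
  one <- disc_ndvi(50, list(c(25, 25)), 10)
  expect_identical(attr(segment_plants(one), "n_components"), 1L)
  # two separate discs -> two records with distinct ids
  two <- disc_ndvi(60, list(c(15, 15), c(45, 45)), 8)
  lab <- segment_plants(two)
  expect_identical(attr(lab, "n_components"), 2L)
  rec <- plant_records(lab)
  expect_identical(nrow(rec), 2L)
  expect_false(anyDuplicated(rec$plant_id) > 0)
})

test_that("the minimum-area filter removes weed-sized blobs", {
  # a 2-pixel blob at gsd 0.01 is far below the 0.05 m-radius disc area
  v <- matrix(0.1, 40, 40)
  v[5:6, 5] <- 0.9
  d2 <- outer((1:40 - 25)^2, (1:40 - 25)^2, "+")
  v[d2 <= 12^2] <- 0.9
  lab <- segment_plants(raster_grid(v, gsd = 0.01))
  expect_identical(attr(lab, "n_components"), 1L)
})

test_that("segmentation is threshold-monotone", {
  set.seed(5)
  sm <- gauss_smooth_for_test(matrix(rnorm(3600), 60, 60)) * 0.4 + 0.45
  g <- raster_grid(sm, gsd = 0.01)
  m1 <- segment_plants(g, veg_threshold = 0.45, min_blob_radius_m = 0)$values > 0
  m2 <- segment_plants(g, veg_threshold = 0.55, min_blob_radius_m = 0)$values > 0
  expect_true(all(m1[m2]))   # raising the threshold never adds pixels
})

test_that("centroids sit at disc centres (symmetry)", {
  one <- disc_ndvi(51, list(c(26, 26)), 10, gsd = 0.01)
  rec <- plant_records(segment_plants(one))
  # world coordinates of pixel (26, 26)
  expect_equal(rec$x_m, one$xmin + 25.5 * 0.01, tolerance = 1e-12)
  expect_equal(rec$y_m, one$ymax - 25.5 * 0.01, tolerance = 1e-12)
})

test_that("merged canopies are split by nominal-grid assignment", {
  # two overlapping discs form a single component
  two <- disc_ndvi(60, list(c(30, 24), c(30, 36)), 9)
  lab <- segment_plants(two)
  expect_identical(attr(lab, "n_components"), 1L)
  expected <- data.frame(plant_id = 1:2, plot_id = 1L,
                         x_m = c(23.5, 35.5) * 0.01,
                         y_m = two$ymax - 29.5 * 0.01)
  rec <- plant_records(lab, expected = expected)
  expect_identical(nrow(rec), 2L)
  off <- sqrt((rec$x_m - expected$x_m)^2 + (rec$y_m - expected$y_m)^2)
  expect_true(all(off < 0.05))
})

test_that("synthetic field plants are recovered near their true positions", {
  rec <- tiny_records()
  pos <- nominal_positions(tiny_layout())
  expect_identical(nrow(rec), nrow(pos))
  off <- sqrt((rec$x_m - pos$x_m)^2 + (rec$y_m - pos$y_m)^2)
  expect_true(all(off < 0.05))
})

test_that("ROI pixel count matches brute-force lattice enumeration", {
  # centroid exactly on a pixel centre, radius 0.20 m at gsd 0.01 m
  g <- raster_grid(matrix(7, 101, 101), gsd = 0.01)
  centre <- list(x_m = g$xmin + 50.5 * 0.01, y_m = g$ymax - 50.5 * 0.01)
  roi <- extract_roi(g, centre, radius_m = 0.20)
  expect_identical(length(roi$values), disc_lattice_count(20))
  expect_true(all(roi$values == 7))
})

test_that("edge ROIs clip without error and empty ROIs fail", {
  g <- raster_grid(matrix(1, 50, 50), gsd = 0.01)
  full <- extract_roi(g, list(x_m = 0.25, y_m = 0.25), radius_m = 0.1)
  edge <- extract_roi(g, list(x_m = 0.005, y_m = 0.25), radius_m = 0.1)
  expect_lt(length(edge$values), length(full$values))
  expect_gt(length(edge$values), 0)
  expect_error(extract_roi(g, list(x_m = 5, y_m = 5), radius_m = 0.1),
               "extraction error")
})

test_that("ROI geometry depends only on the grid, not the map", {
  scene <- tiny_scene()
  rec <- tiny_records()[1, ]
  roi_ph <- extract_roi(get_map(scene, "0618", "ph"), rec)
  roi_nd <- extract_roi(get_map(scene, "0618", "ndvi"), rec)
  expect_identical(roi_ph$rows, roi_nd$rows)
  expect_identical(roi_ph$cols, roi_nd$cols)
})
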
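mk <- function(v, gsd = 0.1) raster_grid(v, gsd = gsd, units = "m")

test_that("DTM equals DSM on plant-free fields and constants interpolate exactly", {
  # constant DSM with vegetation blobs
  dsm <- mk(matrix(10, 30, 30))
  nd <- matrix(0.02, 30, 30)
  nd[10:15, 10:15] <- 0.8
  nd[22:26, 5:9] <- 0.7
  dtm <- estimate_dtm(dsm, mk(nd))
  expect_equal(dtm$values, matrix(10, 30, 30), tolerance = 1e-10)
  # tilted plane, no vegetation at all
  plane <- outer(1:30, 1:30, function(i, j) 3 + 0.2 * i - 0.1 * j)
  dtm2 <- estimate_dtm(mk(plane), mk(matrix(0.05, 30, 30)))
  expect_identical(dtm2$values, plane)
  # no soil pixels at all -> estimation error
  expect_error(estimate_dtm(dsm, mk(matrix(0.9, 30, 30))), "estimation error")
})

test_that("harmonic infill reproduces planar terrain under interior holes", {
  plane <- outer(1:40, 1:40, function(i, j) 5 + 0.3 * i + 0.07 * j)
  nd <- matrix(0.05, 40, 40)
  nd[8:14, 8:14] <- 0.9
  nd[25:33, 20:30] <- 0.9
  dtm <- estimate_dtm(mk(plane), mk(nd))
  expect_lt(max(abs(dtm$values - plane)), 1e-6)
})

test_that("plant height is DSM - DTM with negatives clipped to zero", {
  dsm <- mk(matrix(c(10.5, 10.0, 9.98, 11.2), 2, 2))
  dtm <- mk(matrix(10.0, 2, 2))
  ph <- plant_height(dsm, dtm)
  expect_equal(ph$values, matrix(c(0.5, 0, 0, 1.2), 2, 2))
  expect_equal(plant_height(dtm, dtm)$values, matrix(0, 2, 2))
  expect_error(plant_height(dsm, mk(matrix(0, 3, 3))), "alignment")
})

test_that("soil-line slope recovers exact and degenerate relations", {
  set.seed(3)
  red <- mk(matrix(runif(400, 0.1, 0.3), 20, 20))
  nir <- mk(1.3 * red$values)
  mask <- matrix(TRUE, 20, 20)
  sl <- estimate_soil_line(red, nir, mask)
  expect_equal(sl$slope_a, 1.3, tolerance = 1e-10)
  expect_equal(sl$intercept, 0, tolerance = 1e-10)
  # NIR constant over soil -> slope 0
  sl0 <- estimate_soil_line(red, mk(matrix(0.25, 20, 20)), mask)
  expect_equal(sl0$slope_a, 0, tolerance = 1e-12)
  # degenerate: all Red equal
  expect_error(estimate_soil_line(mk(matrix(0.2, 20, 20)), nir, mask),
               "degenerate")
  # fewer than 2 soil pixels
  m1 <- matrix(FALSE, 20, 20); m1[1] <- TRUE
  expect_error(estimate_soil_line(red, nir, m1), "estimation error")
})

test_that("vegetation indices match their closed forms and handle nodata", {
  nir <- mk(matrix(0.5, 2, 2)); red <- mk(matrix(0.1, 2, 2))
  ndvi <- vegetation_index(list(nir = nir, red = red), "ndvi")
  expect_equal(ndvi$values[1, 1], 0.4 / 0.6, tolerance = 1e-12)
  # NIR = Green -> GNDVI 0
  gn <- vegetation_index(list(nir = nir, green = nir), "gndvi")
  expect_equal(gn$values, matrix(0, 2, 2))
  # WDVI = NIR - a Red
  wd <- vegetation_index(list(nir = mk(matrix(0.4, 2, 2)),
                              red = mk(matrix(0.2, 2, 2))),
                         "wdvi", soil_line = 1.3)
  expect_equal(wd$values[1, 1], 0.14, tolerance = 1e-12)
  # zero denominator -> nodata, not 0
  z <- vegetation_index(list(nir = mk(matrix(0, 2, 2)), red = mk(matrix(0, 2, 2))), "ndvi")
  expect_true(all(is.na(z$values)))
  expect_error(vegetation_index(list(nir = nir), "ndvi"), "missing-map")
})

test_that("NDVI/GNDVI stay in [-1, 1] and nodata propagates", {
  set.seed(11)
  nv <- matrix(runif(900), 30, 30); rv <- matrix(runif(900), 30, 30)
  nv[c(5, 100)] <- NA
  ndvi <- vegetation_index(list(nir = mk(nv), red = mk(rv)), "ndvi")
  ok <- !is.na(ndvi$values)
  expect_true(all(ndvi$values[ok] >= -1 & ndvi$values[ok] <= 1))
  expect_true(all(is.na(ndvi$values[c(5, 100)])))
})

test_that("synthetic field: DTM error is at sensor-noise scale and the soil line is recovered", {
  sim <- tiny_sim()
  scene <- tiny_scene()
  smask <- soil_mask_truth(sim)
  noise <- sim$growth$noise_sd
  for (d in c("0524", "0702")) {
    dtm <- get_map(scene, d, "dtm")$values
    err <- dtm - sim$terrain$values
    veg <- !smask[[d]]
    expect_lt(sqrt(mean(err[veg]^2)), 2 * noise)
    # far below canopy height (~0.7 m)
    expect_lt(max(abs(err[veg])), 0.1)
  }
  slopes <- sapply(attr(scene, "soil_lines"), function(s) s$slope_a)
  expect_true(all(abs(slopes - sim$growth$soil_a_true) < 0.05))
  # derived plant height is nonnegative everywhere
  for (d in scene$dates)
    expect_true(all(get_map(scene, d, "ph")$values >= 0, na.rm = TRUE))
})
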
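test_that("plant count equals the layout product for any layout", {
  expect_identical(n_plants(field_layout()), 210L)
  expect_identical(nrow(nominal_positions(field_layout())), 210L)
  set.seed(2)
  for (i in 1:5) {
    lay <- field_layout(n_plots = sample(1:4, 1), rows_per_plot = sample(1:6, 1),
                        hills_per_row = sample(1:10, 1))
    expect_identical(nrow(nominal_positions(lay)), n_plants(lay))
  }
})

test_that("generation is bit-identical under a fixed seed", {
  lay <- field_layout(n_plots = 1, rows_per_plot = 1, hills_per_row = 2)
  a <- generate_field(lay, growth_params(), synthetic_truth(), seed = 42)
  b <- generate_field(lay, growth_params(), synthetic_truth(), seed = 42)
  expect_identical(a$yields, b$yields)
  for (d in c("0524", "0724"))
    for (nm in c("nir", "red", "dsm"))
      expect_identical(get_map(a$scene, d, nm)$values,
                       get_map(b$scene, d, nm)$values)
  c2 <- generate_field(lay, growth_params(), synthetic_truth(), seed = 43)
  expect_false(identical(a$yields, c2$yields))
})

test_that("zero trait noise makes yields the exact linear predictor of the causal features", {
  sim <- generate_field(tiny_layout(), growth_params(),
                        synthetic_truth(noise_sd = c(SM = 0, FW = 0, FN = 0)),
                        seed = 55)
  tr <- sim$truth
  pred <- sweep(tr$causal_matrix %*% tr$coefficients, 2, tr$intercepts, "+")
  expect_equal(sim$yields$SM, unname(pred[, "SM"]), tolerance = 1e-10)
  expect_equal(sim$yields$FW, unname(pred[, "FW"]), tolerance = 1e-10)
  expect_equal(sim$yields$FN, unname(pmax(0, round(pred[, "FN"]))))
  # regressing the yields on the causal features recovers the coefficients
  fit <- lm(sim$yields$SM ~ tr$causal_matrix)
  expect_equal(unname(coef(fit)[-1]), unname(tr$coefficients[, "SM"]),
               tolerance = 1e-6)
  expect_equal(unname(coef(fit)[1]), unname(tr$intercepts["SM"]),
               tolerance = 1e-6)
})

test_that("unproducible causal feature names raise configuration errors", {
  expect_error(generate_field(tiny_layout(), growth_params(),
                              synthetic_truth(causal_features = "NDVI_AVE_0101",
                                              rel_weights = 1),
                              seed = 1),
               "configuration error")
  expect_error(generate_field(tiny_layout(), growth_params(),
                              synthetic_truth(causal_features = "NDVI_FOO_0618",
                                              rel_weights = 1),
                              seed = 1),
               "configuration error")
})

test_that("soil-mask truth shrinks with growth and is all-true without plants", {
  sim <- tiny_sim()
  masks <- soil_mask_truth(sim)
  frac <- sapply(masks, mean)
  # monotone non-increasing until the height asymptote is reached
  sat <- which(sim$growth$doy >= sim$growth$ph_midpoint_doy + 4 / sim$growth$ph_rate)[1]
  if (is.na(sat)) sat <- length(frac)
  expect_true(all(diff(frac[1:sat]) <= 1e-12))
  # a plant-centre pixel at peak growth is canopy, not soil
  last <- sim$scene$dates[length(sim$scene$dates)]
  rc <- world_to_pixel(sim$terrain, sim$plants$x_m[1], sim$plants$y_m[1])
  expect_false(masks[[last]][rc[1, "row"], rc[1, "col"]])
  # no plants at all -> all-true mask
  empty <- generate_field(field_layout(n_plots = 1, rows_per_plot = 0,
                                       hills_per_row = 0),
                          growth_params(), synthetic_truth(), seed = 5)
  expect_true(all(soil_mask_truth(empty)[["0618"]]))
})

test_that("mean NDVI over canopy peaks at the configured date", {
  sim <- tiny_sim()
  scene <- tiny_scene()
  mn <- sapply(scene$dates, function(d) {
    canopy <- sim$canopy[[d]] > 0.5
    mean(get_map(scene, d, "ndvi")$values[canopy], na.rm = TRUE)
  })
  peak_doy <- scene$doy[which.max(mn)]
  gap <- max(diff(scene$doy))
  expect_lte(abs(peak_doy - sim$growth$ndvi_peak_doy), gap)
})
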
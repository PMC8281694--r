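# Seeded synthetic multi-date field generator with known causal structure.
#
# The generator emulates a three-replicate open-field tomato trial: 5 x 5 m
# plots, five rows of hills at 0.40 m spacing (210 plants in total), ten
# acquisition dates across the season, sigmoid height growth saturating near
# flowering (~DOY 160), vegetation indices peaking in early/mid July and then
# declining, and plant-level yields generated as a linear rule over a known
# subset of features evaluated on the generated rasters through the real
# feature engine.

#' Field layout of a synthetic trial
#'
#' @param n_plots replicate plots (default 3).
#' @param plot_size_m nominal plot edge, m (informational; the raster extent
#'   is derived from rows/hills/spacings plus a margin).
#' @param rows_per_plot rows of hills per plot (default 5).
#' @param hills_per_row hills (plants) per row (default 14, so that
#'   3 x 5 x 14 = 210).
#' @param hill_spacing_m within-row spacing, m (default 0.40).
#' @param row_spacing_m between-row spacing, m (default 1.0).
#' @param gsd_m ground sampling distance, m/pixel (default 0.02).
#' @param margin_m bare-soil margin around each plot, m (default 0.5).
#' @param plot_gap_m bare-soil gap between plots, m (default 1.0).
#' @return list of class `field_layout`.
#' @export
field_layout <- function(n_plots = 3L, plot_size_m = 5, rows_per_plot = 5L,
                         hills_per_row = 14L, hill_spacing_m = 0.40,
                         row_spacing_m = 1.0, gsd_m = 0.02,
                         margin_m = 0.5, plot_gap_m = 1.0) {
  stopifnot(gsd_m > 0, hill_spacing_m > 0, row_spacing_m > 0,
            n_plots >= 1, rows_per_plot >= 0, hills_per_row >= 0)
  structure(list(n_plots = as.integer(n_plots), plot_size_m = plot_size_m,
                 rows_per_plot = as.integer(rows_per_plot),
                 hills_per_row = as.integer(hills_per_row),
                 hill_spacing_m = hill_spacing_m, row_spacing_m = row_spacing_m,
                 gsd_m = gsd_m, margin_m = margin_m, plot_gap_m = plot_gap_m),
            class = "field_layout")
}

#' Total plant count of a layout
#' @param layout a `field_layout`.
#' @return `n_plots * rows_per_plot * hills_per_row`.
#' @export
n_plants <- function(layout)
  layout$n_plots * layout$rows_per_plot * layout$hills_per_row

#' Nominal transplant positions of a layout
#'
#' @param layout a `field_layout`.
#' @return data frame `plant_id`, `plot_id`, `row`, `hill`, `x_m`, `y_m`.
#' @export
nominal_positions <- function(layout) {
  W_in <- max(layout$hills_per_row - 1, 0) * layout$hill_spacing_m
  H_in <- max(layout$rows_per_plot - 1, 0) * layout$row_spacing_m
  H <- H_in + 2 * layout$margin_m
  field_h <- layout$n_plots * H + (layout$n_plots - 1) * layout$plot_gap_m
  out <- list(); id <- 0L
  for (p in seq_len(layout$n_plots)) {
    y_top <- field_h - (p - 1) * (H + layout$plot_gap_m)
    for (r in seq_len(layout$rows_per_plot)) {
      y <- y_top - layout$margin_m - (r - 1) * layout$row_spacing_m
      for (h in seq_len(layout$hills_per_row)) {
        id <- id + 1L
        out[[id]] <- data.frame(plant_id = id, plot_id = p, row = r, hill = h,
                                x_m = layout$margin_m + (h - 1) * layout$hill_spacing_m,
                                y_m = y)
      }
    }
  }
  if (id == 0L) return(data.frame(plant_id = integer(), plot_id = integer(),
                                  row = integer(), hill = integer(),
                                  x_m = numeric(), y_m = numeric()))
  do.call(rbind, out)
}

field_extent <- function(layout) {
  W <- max(layout$hills_per_row - 1, 0) * layout$hill_spacing_m + 2 * layout$margin_m
  H_in <- max(layout$rows_per_plot - 1, 0) * layout$row_spacing_m
  H <- (H_in + 2 * layout$margin_m) * layout$n_plots +
    (layout$n_plots - 1) * layout$plot_gap_m
  list(width = W, height = H,
       nc = as.integer(ceiling(W / layout$gsd_m)),
       nr = as.integer(ceiling(H / layout$gsd_m)))
}

#' Growth and reflectance parameters of the synthetic season
#'
#' Plant height follows a logistic curve `A / (1 + exp(-rate (t - t_mid)))`
#' saturating shortly after the flowering window; the vegetated NDVI/GNDVI
#' trajectories are Gaussian-in-time bumps peaking in early July (DOY 184)
#' and the vegetated NIR trajectory peaks later (DOY 194) so that WDVI peaks
#' with it; both decline afterwards as leaves senesce. Bare soil sits on the
#' soil line `NIR = a_true * Red + b`.
#'
#' @param dates acquisition dates `"MMDD"` (default the ten dates May 24 to
#'   July 24).
#' @param year season year (default 2020).
#' @param ph_asymptote_mean,ph_asymptote_sd per-plant final height, m.
#' @param ph_midpoint_doy,ph_rate logistic midpoint (DOY) and rate (1/day).
#' @param ndvi_peak_doy,gndvi_peak_doy,wdvi_peak_doy trajectory peaks (DOY).
#' @param ndvi_base,gndvi_base vegetated index baselines.
#' @param vi_amplitude_mean,vi_amplitude_sd per-plant index amplitude.
#' @param vi_width_days temporal width of the index bump.
#' @param nir_base,nir_amplitude vegetated NIR trajectory (drives WDVI).
#' @param canopy_sigma_m canopy footprint Gaussian sd, m (truncated at 3 sd).
#' @param soil_a_true,soil_intercept,soil_red_mean soil-line truth and mean
#'   soil red reflectance.
#' @param texture_corr_length_px correlation length of the within-canopy
#'   texture random field, pixels.
#' @param texture_amp_range per-plant texture amplitude range (uniform).
#' @param noise_sd DSM white-noise sd, m.
#' @param refl_noise_sd reflectance white-noise sd.
#' @return list of class `growth_params`.
#' @export
growth_params <- function(dates = c("0524", "0530", "0605", "0611", "0618",
                                    "0626", "0702", "0712", "0716", "0724"),
                          year = 2020,
                          ph_asymptote_mean = 0.70, ph_asymptote_sd = 0.07,
                          ph_midpoint_doy = 150, ph_rate = 0.10,
                          ndvi_peak_doy = 184, gndvi_peak_doy = 184,
                          wdvi_peak_doy = 194,
                          ndvi_base = 0.60, gndvi_base = 0.48,
                          vi_amplitude_mean = 0.35, vi_amplitude_sd = 0.03,
                          vi_width_days = 26,
                          nir_base = 0.25, nir_amplitude = 0.30,
                          canopy_sigma_m = 0.12,
                          soil_a_true = 1.1, soil_intercept = 0.0,
                          soil_red_mean = 0.20,
                          texture_corr_length_px = 3,
                          texture_amp_range = c(0.04, 0.12),
                          noise_sd = 0.005, refl_noise_sd = 0.004) {
  doy <- date_to_doy(dates, year)
  if (any(diff(doy) <= 0)) stop("dates must be strictly increasing")
  stopifnot(ph_asymptote_mean > 0, ph_asymptote_sd >= 0, vi_amplitude_sd >= 0,
            noise_sd >= 0, refl_noise_sd >= 0)
  structure(as.list(environment()), class = "growth_params")
}

#' Ground-truth causal structure of synthetic yields
#'
#' Yields are a linear rule over named feature columns (evaluated on the
#' generated rasters through the package's own feature engine) plus Gaussian
#' noise. Relative weights act on standardized features and are rescaled so
#' the linear predictor has coefficient of variation `cv` about each trait
#' mean; the noise sd is either given explicitly (per trait, same units as
#' the trait) or derived from `target_r2`, the intended share of yield
#' variance explained by the causal features.
#'
#' @param causal_features feature-column names under the
#'   `<MAP>_<STAT>_<MMDD>` / `<MAP>_GR_<D1>-<D2>` convention.
#' @param rel_weights relative weights, one per causal feature.
#' @param trait_means mean yields: SM and FW in kg/plant, FN in fruit/plant.
#' @param cv coefficient of variation of the linear predictor (default 0.2).
#' @param target_r2 intended truth R-squared (default 0.8); ignored when
#'   `noise_sd` is given.
#' @param noise_sd optional explicit per-trait noise sd (named like
#'   `trait_means`); 0 gives noiseless yields.
#' @return list of class `synthetic_truth`.
#' @export
synthetic_truth <- function(causal_features = c("NDVI_AVE_0618", "PH_AVE_0626",
                                                "WDVI_RANGE_0618", "NDVI_SV_0712",
                                                "GNDVI_RANGE_0716"),
                            rel_weights = c(0.5, 0.45, 0.4, 0.35, 0.3),
                            trait_means = c(SM = 1.6, FW = 2.4, FN = 28),
                            cv = 0.2, target_r2 = 0.8, noise_sd = NULL) {
  if (length(rel_weights) != length(causal_features))
    stop("one weight per causal feature required")
  if (!is.null(noise_sd) && any(noise_sd < 0)) stop("noise_sd must be >= 0")
  structure(list(causal_features = causal_features, rel_weights = rel_weights,
                 trait_means = trait_means, cv = cv, target_r2 = target_r2,
                 noise_sd = noise_sd), class = "synthetic_truth")
}

# seeded Gaussian random field: white noise smoothed by a separable Gaussian
# kernel of the given correlation length, standardized to sd 1
gauss_field <- function(nr, nc, corr_px) {
  if (corr_px <= 0) return(matrix(stats::rnorm(nr * nc), nr, nc))
  R <- ceiling(3 * corr_px)
  kern <- stats::dnorm(-R:R, sd = corr_px)
  kern <- kern / sum(kern)
  pad <- matrix(stats::rnorm((nr + 2 * R) * (nc + 2 * R)), nr + 2 * R, nc + 2 * R)
  sm <- apply(pad, 2, function(col) stats::filter(col, kern, sides = 2))
  sm <- t(apply(sm, 1, function(row) stats::filter(row, kern, sides = 2)))
  out <- sm[(R + 1):(R + nr), (R + 1):(R + nc)]
  out / stats::sd(out)
}

logistic_height <- function(doy, A, t_mid, rate)
  A / (1 + exp(-rate * (doy - t_mid)))

vi_bump <- function(doy, peak, width) exp(-(doy - peak)^2 / (2 * width^2))

#' Generate a synthetic multi-date field with known yields
#'
#' Builds, for every acquisition date, a DSM (planar terrain plus per-plant
#' Gaussian canopy bumps scaled by a logistic height curve, plus white noise)
#' and five reflectance bands in which vegetated pixels follow the configured
#' vegetation-index trajectories and bare-soil pixels sit on the configured
#' soil line. Plant-level yields are computed as a linear predictor over the
#' truth's causal features — evaluated on the generated rasters through the
#' real feature engine — plus Gaussian noise; fruit number is the rounded,
#' floored-at-zero version of its predictor. Identical seeds give identical
#' outputs.
#'
#' @param layout a [field_layout()].
#' @param growth a [growth_params()].
#' @param truth_spec a [synthetic_truth()].
#' @param seed integer RNG seed.
#' @param n_levels gray levels used when causal features include GLCM
#'   statistics (default 32).
#' @return object of class `synthetic_field`: `scene` (raw bands + dsm),
#'   `yields` (plant_id, SM, FW, FN), `plants` (plant records with true
#'   centroids), `truth` (realized raw-scale coefficients, intercepts, noise
#'   sds, seed), `terrain` (raster), `canopy` (per-date canopy-fraction
#'   matrices), `truth_maps` (per-date true ph/ndvi/gndvi/wdvi rasters),
#'   `layout`, `growth`.
#' @export
generate_field <- function(layout = field_layout(), growth = growth_params(),
                           truth_spec = synthetic_truth(), seed = 1L,
                           n_levels = 32) {
  set.seed(seed)
  ext <- field_extent(layout)
  nr <- ext$nr; nc <- ext$nc
  gsd <- layout$gsd_m
  ymax <- nr * gsd
  pos <- nominal_positions(layout)
  np <- nrow(pos)
  doy_all <- growth$doy
  nd <- length(growth$dates)

  # per-plant parameters
  A <- stats::rnorm(np, growth$ph_asymptote_mean, growth$ph_asymptote_sd)
  A <- pmax(A, 0.1 * growth$ph_asymptote_mean)
  amp_ndvi <- stats::rnorm(np, growth$vi_amplitude_mean, growth$vi_amplitude_sd)
  amp_gndvi <- stats::rnorm(np, growth$vi_amplitude_mean, growth$vi_amplitude_sd)
  amp_nir <- growth$nir_amplitude * (1 + stats::rnorm(np, 0, 0.1))
  tex_amp <- stats::runif(np, growth$texture_amp_range[1], growth$texture_amp_range[2])

  xs <- (seq_len(nc) - 0.5) * gsd
  ys <- ymax - (seq_len(nr) - 0.5) * gsd

  # static terrain: gentle plane
  terrain <- outer(ys, xs, function(y, x) 50 + 0.005 * x - 0.003 * y)

  scene <- scene_stack(growth$dates, year = growth$year)
  canopy <- list(); truth_maps <- list()

  for (di in seq_len(nd)) {
    d <- growth$dates[di]; t <- doy_all[di]
    h <- logistic_height(t, A, growth$ph_midpoint_doy, growth$ph_rate)
    sig <- growth$canopy_sigma_m * (0.5 + 0.5 * h / A)
    gmat <- matrix(0, nr, nc)
    phmat <- matrix(0, nr, nc)
    bestg <- matrix(0, nr, nc)
    pidx <- matrix(0L, nr, nc)
    for (i in seq_len(np)) {
      rad <- 3 * sig[i]
      ci <- which(abs(xs - pos$x_m[i]) <= rad)
      ri <- which(abs(ys - pos$y_m[i]) <= rad)
      if (length(ci) == 0 || length(ri) == 0) next
      d2 <- outer((ys[ri] - pos$y_m[i])^2, (xs[ci] - pos$x_m[i])^2, "+")
      g <- exp(-d2 / (2 * sig[i]^2))
      g[d2 > rad^2] <- 0
      gmat[ri, ci] <- gmat[ri, ci] + g
      # the height bump vanishes at the optical canopy edge (g < 0.15), so
      # pixels classed as soil by NDVI never carry canopy elevation
      phmat[ri, ci] <- phmat[ri, ci] + h[i] * pmax(0, (g - 0.15) / 0.85)
      upd <- g > bestg[ri, ci]
      bg <- bestg[ri, ci]; bg[upd] <- g[upd]; bestg[ri, ci] <- bg
      pi_ <- pidx[ri, ci]; pi_[upd] <- i; pidx[ri, ci] <- pi_
    }
    f <- pmin(gmat, 1)
    canopy[[d]] <- f

    # texture fields (one per optical quantity, per date)
    tau_ndvi <- gauss_field(nr, nc, growth$texture_corr_length_px)
    tau_nir <- gauss_field(nr, nc, growth$texture_corr_length_px)
    tau_gndvi <- gauss_field(nr, nc, growth$texture_corr_length_px)
    tau_ph <- gauss_field(nr, nc, growth$texture_corr_length_px)
    tau_soil <- gauss_field(nr, nc, 10)

    # per-plant target trajectories at this date
    ndvi_t <- growth$ndvi_base + amp_ndvi * vi_bump(t, growth$ndvi_peak_doy, growth$vi_width_days)
    gndvi_t <- growth$gndvi_base + amp_gndvi * vi_bump(t, growth$gndvi_peak_doy, growth$vi_width_days)
    nir_t <- growth$nir_base + amp_nir * vi_bump(t, growth$wdvi_peak_doy, growth$vi_width_days)

    on <- pidx > 0L
    # within-canopy texture builds up with canopy development
    stage <- 0.5 + 0.5 * mean(h / A)
    amp_px <- matrix(0, nr, nc); amp_px[on] <- stage * tex_amp[pidx[on]]
    n_px <- matrix(0, nr, nc); n_px[on] <- ndvi_t[pidx[on]]
    n_px <- pmin(pmax(n_px + 0.4 * amp_px * tau_ndvi, 0.05), 0.97)
    gn_px <- matrix(0, nr, nc); gn_px[on] <- gndvi_t[pidx[on]]
    gn_px <- pmin(pmax(gn_px + 0.4 * amp_px * tau_gndvi, 0.05), 0.97)
    nir_veg <- matrix(growth$nir_base, nr, nc); nir_veg[on] <- nir_t[pidx[on]]
    nir_veg <- nir_veg * (1 + amp_px * tau_nir)
    red_veg <- nir_veg * (1 - n_px) / (1 + n_px)
    green_veg <- nir_veg * (1 - gn_px) / (1 + gn_px)

    # bare soil on the soil line
    red_soil <- growth$soil_red_mean + 0.025 * tau_soil +
      stats::rnorm(nr * nc, 0, growth$refl_noise_sd)
    nir_soil <- growth$soil_a_true * red_soil + growth$soil_intercept +
      stats::rnorm(nr * nc, 0, 0.6 * growth$refl_noise_sd)
    green_soil <- 0.92 * red_soil + stats::rnorm(nr * nc, 0, growth$refl_noise_sd)

    mix <- function(veg, soil) f * veg + (1 - f) * soil
    red <- pmin(pmax(mix(red_veg, red_soil), 0.001), 0.999)
    nir <- pmin(pmax(mix(nir_veg, nir_soil), 0.001), 0.999)
    green <- pmin(pmax(mix(green_veg, green_soil), 0.001), 0.999)
    blue <- pmin(pmax(0.05 + 0.2 * red + stats::rnorm(nr * nc, 0, growth$refl_noise_sd), 0.001), 0.999)
    rededge <- pmin(pmax(0.5 * (red + nir) + stats::rnorm(nr * nc, 0, growth$refl_noise_sd), 0.001), 0.999)

    ph_true <- phmat * (1 + 0.5 * amp_px * tau_ph)
    dsm <- terrain + ph_true + stats::rnorm(nr * nc, 0, growth$noise_sd)

    mk <- function(v, units) raster_grid(v, xmin = 0, ymax = ymax, gsd = gsd, units = units)
    for (nm in c("blue", "green", "red", "rededge", "nir"))
      scene <- set_map(scene, d, nm, mk(get(nm), "reflectance"))
    scene <- set_map(scene, d, "dsm", mk(dsm, "m"))

    tm <- list(ph = mk(pmax(dsm - terrain, 0), "m"))
    tm$ndvi <- vegetation_index(list(nir = mk(nir, "reflectance"), red = mk(red, "reflectance")), "ndvi")
    tm$gndvi <- vegetation_index(list(nir = mk(nir, "reflectance"), green = mk(green, "reflectance")), "gndvi")
    tm$wdvi <- vegetation_index(list(nir = mk(nir, "reflectance"), red = mk(red, "reflectance")),
                                "wdvi", soil_line = growth$soil_a_true)
    truth_maps[[d]] <- tm
  }

  plants <- data.frame(plant_id = pos$plant_id, plot_id = pos$plot_id,
                       x_m = pos$x_m, y_m = pos$y_m,
                       radius_m = rep(0.20, np))

  yields <- NULL; truth <- NULL
  if (np > 0 && length(truth_spec$causal_features) > 0) {
    Xc <- causal_feature_matrix(truth_maps, growth, plants,
                                truth_spec$causal_features, n_levels)
    traits <- names(truth_spec$trait_means)
    mu_j <- colMeans(Xc); sd_j <- apply(Xc, 2, stats::sd)
    sd_j[sd_j == 0] <- 1
    z <- sweep(sweep(Xc, 2, mu_j), 2, sd_j, "/")
    u <- as.numeric(z %*% truth_spec$rel_weights)
    u_sd <- stats::sd(u); if (u_sd == 0) u_sd <- 1
    w_std <- truth_spec$rel_weights * (truth_spec$cv / u_sd)
    coef_raw <- outer(w_std / sd_j, truth_spec$trait_means)  # feature x trait
    rownames(coef_raw) <- truth_spec$causal_features
    colnames(coef_raw) <- traits
    intercepts <- truth_spec$trait_means * (1 - sum(w_std * mu_j / sd_j))
    # re-derive intercepts exactly: mean_t + sum b_jt (x_j - mu_j) form
    intercepts <- truth_spec$trait_means - as.numeric(mu_j %*% coef_raw)
    pred <- sweep(Xc %*% coef_raw, 2, intercepts, "+")
    nsd <- truth_spec$noise_sd
    if (is.null(nsd)) {
      r2 <- truth_spec$target_r2
      nsd <- truth_spec$trait_means * truth_spec$cv * sqrt((1 - r2) / r2)
    }
    nsd <- rep(nsd, length.out = length(traits)); names(nsd) <- traits
    eps <- sapply(traits, function(tr) stats::rnorm(np, 0, nsd[tr]))
    if (np == 1) eps <- matrix(eps, nrow = 1)
    y <- pred + eps
    if ("FN" %in% traits) y[, "FN"] <- pmax(0, round(y[, "FN"]))
    yields <- data.frame(plant_id = plants$plant_id, y)
    truth <- list(causal_features = truth_spec$causal_features,
                  coefficients = coef_raw, intercepts = intercepts,
                  noise_sd = nsd, seed = seed,
                  causal_matrix = Xc, rel_weights = truth_spec$rel_weights)
    class(truth) <- "synthetic_truth_realized"
  }

  structure(list(scene = scene, yields = yields, plants = plants, truth = truth,
                 terrain = raster_grid(terrain, xmin = 0, ymax = ymax,
                                       gsd = gsd, units = "m"),
                 canopy = canopy, truth_maps = truth_maps,
                 layout = layout, growth = growth, seed = seed),
            class = "synthetic_field")
}

# evaluate the requested causal feature columns on the truth maps with the
# real feature primitives (ROI extraction, first-order stats, GLCM engine)
causal_feature_matrix <- function(truth_maps, growth, plants, causal, n_levels) {
  np <- nrow(plants)
  parse1 <- function(nm) {
    parts <- strsplit(nm, "_")[[1]]
    if (length(parts) != 3) stop(sprintf("configuration error: bad causal feature name '%s'", nm))
    list(map = parts[1], stat = parts[2], date = parts[3])
  }
  get_truth_map <- function(map, date) {
    key <- tolower(map)
    if (is.null(truth_maps[[date]]) || is.null(truth_maps[[date]][[key]]))
      stop(sprintf("configuration error: causal feature references unavailable map/date %s/%s", map, date))
    truth_maps[[date]][[key]]
  }
  ave_one <- function(map, date) {
    ras <- get_truth_map(map, date)
    vapply(seq_len(np), function(pi) mean(extract_roi(ras, plants[pi, ])$values), numeric(1))
  }
  X <- matrix(NA_real_, np, length(causal), dimnames = list(NULL, causal))
  for (k in seq_along(causal)) {
    nm <- causal[k]
    p <- parse1(nm)
    if (p$stat == "GR") {
      dd <- strsplit(p$date, "-")[[1]]
      if (length(dd) != 2 || !all(dd %in% growth$dates))
        stop(sprintf("configuration error: bad growth-rate causal feature '%s'", nm))
      ddoy <- growth$doy[match(dd, growth$dates)]
      X[, k] <- (ave_one(p$map, dd[2]) - ave_one(p$map, dd[1])) / diff(ddoy)
    } else if (p$stat %in% FIRST_ORDER_STATS) {
      if (!p$date %in% growth$dates)
        stop(sprintf("configuration error: causal date '%s' not acquired", p$date))
      ras <- get_truth_map(p$map, p$date)
      X[, k] <- vapply(seq_len(np), function(pi)
        first_order(extract_roi(ras, plants[pi, ])$values)[p$stat], numeric(1))
    } else if (p$stat %in% GLCM_STATS) {
      if (!p$date %in% growth$dates)
        stop(sprintf("configuration error: causal date '%s' not acquired", p$date))
      ras <- get_truth_map(p$map, p$date)
      X[, k] <- vapply(seq_len(np), function(pi) {
        roi <- extract_roi(ras, plants[pi, ])
        q <- quantize(roi$patch, roi$mask, n_levels = n_levels)
        tryCatch(glcm_features(glcm(q, n_levels = n_levels))[p$stat],
                 error = function(e) constant_glcm_features()[p$stat])
      }, numeric(1))
    } else {
      stop(sprintf("configuration error: unknown statistic in causal feature '%s'", nm))
    }
  }
  X
}

#' True soil mask of a synthetic field
#'
#' True where no canopy contributes above `eps`, per date; lets tests compare
#' an estimated terrain model against the known truth.
#'
#' @param sim a `synthetic_field`.
#' @param eps canopy-fraction threshold (default 1e-3).
#' @return named list (by date) of logical matrices.
#' @export
soil_mask_truth <- function(sim, eps = 1e-3) {
  lapply(sim$canopy, function(f) f < eps)
}
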
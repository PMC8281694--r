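# Terrain estimation, plant height, soil line and vegetation indices.

#' Estimate the digital terrain model from a DSM and an NDVI map
#'
#' Soil pixels (NDVI below `soil_threshold`) keep their DSM elevation; the
#' elevation under vegetation is reconstructed by harmonic (Laplace) infill:
#' each vegetation pixel is required to equal the mean of its 4-neighbours,
#' with soil pixels as Dirichlet boundary values, and the resulting sparse
#' linear system is solved exactly. Harmonic infill is deterministic and
#' reproduces planar terrain exactly, since planes satisfy the Laplace
#' equation.
#'
#' @param dsm `raster_grid` of surface elevation (m), canopy included.
#' @param ndvi aligned `raster_grid` of NDVI.
#' @param soil_threshold NDVI below which a pixel is treated as bare soil
#'   (default 0.1).
#' @return a `raster_grid` DTM with no missing data inside the field extent.
#' @export
estimate_dtm <- function(dsm, ndvi, soil_threshold = 0.1) {
  check_aligned(dsm, ndvi)
  v <- dsm$values
  soil <- !is.na(ndvi$values) & ndvi$values < soil_threshold & !is.na(v)
  if (!any(soil)) stop("estimation error: no soil pixels below the NDVI threshold")
  unknown <- !soil
  out <- v
  if (any(unknown)) out[unknown] <- harmonic_fill(v, soil, unknown)
  raster_grid(out, xmin = dsm$xmin, ymax = dsm$ymax, gsd = dsm$gsd, units = "m")
}

# Solve the discrete Laplace equation over `unknown` pixels with Dirichlet
# values taken from `values` at `known` pixels. Raster borders act as
# zero-flux (Neumann) boundaries: the diagonal counts only in-grid neighbours.
harmonic_fill <- function(values, known, unknown) {
  nr <- nrow(values); nc <- ncol(values)
  idx <- matrix(0L, nr, nc)
  m <- sum(unknown)
  idx[unknown] <- seq_len(m)
  ui <- which(unknown, arr.ind = TRUE)
  b <- numeric(m)
  deg <- integer(m)
  ti <- tj <- integer(0); tx <- numeric(0)
  for (sh in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    ni <- ui[, 1] + sh[1]; nj <- ui[, 2] + sh[2]
    inside <- ni >= 1L & ni <= nr & nj >= 1L & nj <= nc
    deg <- deg + inside
    nk <- cbind(ni[inside], nj[inside])
    rows <- which(inside)
    nidx <- idx[nk]
    isu <- nidx > 0L
    # unknown neighbour -> off-diagonal -1; known neighbour -> rhs
    ti <- c(ti, rows[isu]); tj <- c(tj, nidx[isu]); tx <- c(tx, rep(-1, sum(isu)))
    kn <- !isu
    if (any(kn)) {
      vb <- values[nk[kn, , drop = FALSE]]
      vb[is.na(vb)] <- mean(values[known])   # nodata neighbour: field mean
      bi <- rows[kn]
      b[bi] <- b[bi] + vb
    }
  }
  A <- Matrix::sparseMatrix(i = c(seq_len(m), ti), j = c(seq_len(m), tj),
                            x = c(pmax(deg, 1L), tx), dims = c(m, m))
  as.numeric(Matrix::solve(A, b))
}

#' Plant-height map
#'
#' Elementwise `DSM - DTM`; negative differences (sensor/interpolation noise
#' placing the surface below the terrain) are clipped to zero.
#'
#' @param dsm,dtm aligned `raster_grid`s of surface and terrain elevation (m).
#' @return a `raster_grid` of canopy height (m).
#' @export
plant_height <- function(dsm, dtm) {
  check_aligned(dsm, dtm)
  ph <- pmax(dsm$values - dtm$values, 0)
  raster_grid(ph, xmin = dsm$xmin, ymax = dsm$ymax, gsd = dsm$gsd, units = "m")
}

#' Estimate the soil-line slope from bare-soil pixels
#'
#' Fits NIR = intercept + a * Red by least squares over the supplied soil
#' pixels; `a` is the slope used by the weighted difference vegetation index.
#'
#' @param red,nir aligned reflectance `raster_grid`s.
#' @param soil_mask logical matrix marking bare-soil pixels.
#' @return a list of class `soil_line`: `slope_a`, `intercept`,
#'   `n_soil_pixels`.
#' @export
estimate_soil_line <- function(red, nir, soil_mask) {
  check_aligned(red, nir)
  ok <- soil_mask & !is.na(red$values) & !is.na(nir$values)
  x <- red$values[ok]; y <- nir$values[ok]
  if (length(x) < 2) stop("estimation error: need at least 2 soil pixels")
  vx <- stats::var(x)
  if (vx == 0) stop("estimation error: degenerate soil pixels (all Red equal)")
  a <- stats::cov(x, y) / vx
  structure(list(slope_a = a, intercept = mean(y) - a * mean(x),
                 n_soil_pixels = length(x)), class = "soil_line")
}

#' Compute a vegetation-index map
#'
#' * `ndvi  = (NIR - Red)   / (NIR + Red)`
#' * `gndvi = (NIR - Green) / (NIR + Green)`
#' * `wdvi  = NIR - a * Red`, `a` the soil-line slope.
#'
#' Pixels with a zero denominator become missing rather than 0, so they can
#' never contaminate ROI statistics.
#'
#' @param maps named list with the required reflectance `raster_grid`s
#'   (`nir` and `red` and/or `green`).
#' @param which one of `"ndvi"`, `"gndvi"`, `"wdvi"`.
#' @param soil_line a `soil_line` object or a numeric slope constant
#'   (required for `wdvi`).
#' @return a `raster_grid`, unitless.
#' @export
vegetation_index <- function(maps, which = c("ndvi", "gndvi", "wdvi"),
                             soil_line = NULL) {
  which <- match.arg(which)
  need <- switch(which, ndvi = c("nir", "red"), gndvi = c("nir", "green"),
                 wdvi = c("nir", "red"))
  for (nm in need)
    if (is.null(maps[[nm]])) stop(sprintf("missing-map error: band '%s' required for %s", nm, which))
  nir <- maps$nir
  other <- maps[[setdiff(need, "nir")]]
  check_aligned(nir, other)
  if (which == "wdvi") {
    a <- if (inherits(soil_line, "soil_line")) soil_line$slope_a else soil_line
    if (is.null(a) || !is.finite(a)) stop("wdvi requires a soil-line slope")
    v <- nir$values - a * other$values
  } else {
    den <- nir$values + other$values
    v <- (nir$values - other$values) / den
    v[!is.na(den) & den == 0] <- NA_real_
  }
  raster_grid(v, xmin = nir$xmin, ymax = nir$ymax, gsd = nir$gsd, units = "unitless")
}

#' Derive DTM, plant-height and vegetation-index maps for every date
#'
#' For each date of a scene holding the raw bands and DSM, computes NDVI and
#' GNDVI, segments soil at `NDVI < soil_threshold`, fits the per-date soil
#' line (unless a constant slope is supplied), computes WDVI, estimates the
#' DTM by harmonic infill, and derives the plant-height map.
#'
#' @param scene a `scene_stack` with `nir`, `red`, `green`, `dsm` at each date.
#' @param soil_threshold NDVI threshold for bare soil (default 0.1).
#' @param soil_a optional constant soil-line slope overriding per-date
#'   estimation.
#' @return the scene with `ndvi`, `gndvi`, `wdvi`, `dtm`, `ph` maps added and
#'   an attribute `soil_lines` (named list per date).
#' @export
derive_scene_maps <- function(scene, soil_threshold = 0.1, soil_a = NULL) {
  soil_lines <- list()
  for (d in scene$dates) {
    maps <- scene$maps[[d]]
    ndvi <- vegetation_index(maps, "ndvi")
    gndvi <- vegetation_index(maps, "gndvi")
    soil <- !is.na(ndvi$values) & ndvi$values < soil_threshold
    sl <- if (is.null(soil_a)) estimate_soil_line(maps$red, maps$nir, soil)
          else structure(list(slope_a = soil_a, intercept = NA_real_,
                              n_soil_pixels = sum(soil)), class = "soil_line")
    wdvi <- vegetation_index(maps, "wdvi", soil_line = sl)
    dtm <- estimate_dtm(maps$dsm, ndvi, soil_threshold = soil_threshold)
    ph <- plant_height(maps$dsm, dtm)
    scene <- set_map(scene, d, "ndvi", ndvi)
    scene <- set_map(scene, d, "gndvi", gndvi)
    scene <- set_map(scene, d, "wdvi", wdvi)
    scene <- set_map(scene, d, "dtm", dtm)
    scene <- set_map(scene, d, "ph", ph)
    soil_lines[[d]] <- sl
  }
  attr(scene, "soil_lines") <- soil_lines
  scene
}
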
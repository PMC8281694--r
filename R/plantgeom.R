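# Plant segmentation, centroid records, and circular-ROI pixel extraction.

#' Segment plant parts from an NDVI map
#'
#' Thresholds the NDVI map at `veg_threshold`, labels 8-connected components,
#' and removes components below a minimum area. The area filter is the
#' deterministic analogue of manual weed removal: anything smaller than a
#' disc of radius `min_blob_radius_m` cannot be a transplanted crop plant.
#'
#' @param ndvi a `raster_grid`.
#' @param veg_threshold NDVI above which a pixel counts as vegetation
#'   (default 0.5).
#' @param min_blob_radius_m radius (m) of the smallest disc kept
#'   (default 0.05 m).
#' @return an integer-valued `raster_grid` of component labels (0 =
#'   background) with attribute `n_components`; labels are numbered 1..K in
#'   raster scan order of each component's first pixel. An empty mask yields
#'   zero components with a warning.
#' @export
segment_plants <- function(ndvi, veg_threshold = 0.5, min_blob_radius_m = 0.05) {
  mask <- !is.na(ndvi$values) & ndvi$values > veg_threshold
  if (!any(mask)) {
    warning("segmentation warning: empty vegetation mask")
    lab <- matrix(0L, nrow(ndvi$values), ncol(ndvi$values))
    out <- raster_grid(lab, xmin = ndvi$xmin, ymax = ndvi$ymax, gsd = ndvi$gsd,
                       units = "label")
    attr(out, "n_components") <- 0L
    return(out)
  }
  lab <- label_components(mask)
  min_area <- pi * (min_blob_radius_m / ndvi$gsd)^2
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_area)
  relab <- integer(length(sizes))
  # renumber kept components by first occurrence in column-major scan order
  first <- vapply(keep, function(k) which(lab == k)[1], integer(1))
  keep <- keep[order(first)]
  relab[keep] <- seq_along(keep)
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  out <- raster_grid(lab, xmin = ndvi$xmin, ymax = ndvi$ymax, gsd = ndvi$gsd,
                     units = "label")
  attr(out, "n_components") <- length(keep)
  out
}

# 8-connected component labelling by iterative minimum-label propagation.
# Deterministic; labels are provisional (renumbered by the caller).
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask] <- seq_len(sum(mask))
  big <- sum(mask) + 1L
  shifts <- list(c(-1L,-1L), c(-1L,0L), c(-1L,1L), c(0L,-1L),
                 c(0L,1L), c(1L,-1L), c(1L,0L), c(1L,1L))
  repeat {
    cur <- lab
    m <- matrix(big, nr, nc); m[mask] <- lab[mask]
    best <- m
    for (sh in shifts) {
      shifted <- matrix(big, nr, nc)
      r1 <- max(1L, 1L + sh[1]); r2 <- min(nr, nr + sh[1])
      c1 <- max(1L, 1L + sh[2]); c2 <- min(nc, nc + sh[2])
      shifted[r1:r2, c1:c2] <- m[(r1:r2) - sh[1], (c1:c2) - sh[2]]
      best <- pmin(best, shifted)
    }
    lab[mask] <- best[mask]
    if (identical(lab, cur)) break
  }
  lab
}

#' Plant records from a label raster
#'
#' Each record carries the plant id, plot id, world-coordinate centroid and
#' the ROI radius. Centroids are the mean world coordinates of a component's
#' pixel centres. When the nominal transplant grid is supplied and canopies
#' have merged (fewer components than expected positions), every vegetated
#' pixel is instead assigned to its nearest nominal position and centroids
#' are recomputed per assignment, restoring one record per plant.
#'
#' @param labels label `raster_grid` from [segment_plants()].
#' @param expected optional data frame of nominal positions with columns
#'   `plant_id`, `plot_id`, `x_m`, `y_m`.
#' @param roi_radius_m ROI radius stored on each record (default 0.20 m).
#' @return data frame: `plant_id`, `plot_id`, `x_m`, `y_m`, `radius_m`.
#' @export
plant_records <- function(labels, expected = NULL, roi_radius_m = 0.20) {
  lv <- labels$values
  on <- which(lv > 0L)
  if (length(on) == 0) stop("no components to derive records from")
  rows <- (on - 1L) %% nrow(lv) + 1L
  cols <- (on - 1L) %/% nrow(lv) + 1L
  px <- labels$xmin + (cols - 0.5) * labels$gsd
  py <- labels$ymax - (rows - 0.5) * labels$gsd
  k <- max(lv)
  if (!is.null(expected) && k < nrow(expected)) {
    # merged canopies: nearest-nominal-position pixel assignment
    assign <- nearest_position(px, py, expected$x_m, expected$y_m)
    cx <- tapply(px, factor(assign, levels = seq_len(nrow(expected))), mean)
    cy <- tapply(py, factor(assign, levels = seq_len(nrow(expected))), mean)
    # plants with no assigned pixel fall back to their nominal position
    cx[is.na(cx)] <- expected$x_m[is.na(cx)]
    cy[is.na(cy)] <- expected$y_m[is.na(cy)]
    return(data.frame(plant_id = expected$plant_id, plot_id = expected$plot_id,
                      x_m = as.numeric(cx), y_m = as.numeric(cy),
                      radius_m = roi_radius_m))
  }
  g <- factor(lv[on], levels = seq_len(k))
  cx <- as.numeric(tapply(px, g, mean))
  cy <- as.numeric(tapply(py, g, mean))
  if (!is.null(expected)) {
    nearest <- nearest_position(cx, cy, expected$x_m, expected$y_m)
    out <- data.frame(plant_id = expected$plant_id[nearest],
                      plot_id = expected$plot_id[nearest],
                      x_m = cx, y_m = cy, radius_m = roi_radius_m)
    out[order(out$plant_id), , drop = FALSE]
  } else {
    data.frame(plant_id = seq_len(k), plot_id = 1L,
               x_m = cx, y_m = cy, radius_m = roi_radius_m)
  }
}

# index of the nearest (xe, ye) position for each (x, y), chunked to bound
# the distance-matrix size
nearest_position <- function(x, y, xe, ye, chunk = 20000L) {
  n <- length(x)
  out <- integer(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    d <- outer(x[s:e], xe, "-")^2 + outer(y[s:e], ye, "-")^2
    out[s:e] <- max.col(-d, ties.method = "first")
  }
  out
}

#' Extract the circular ROI of one plant from a raster
#'
#' Selects every pixel whose centre lies within `radius_m` of the plant
#' centroid (pixel-centre rule, grid-resolution independent). Missing pixels
#' are dropped from `values` but their positions are retained in the patch
#' mask so texture computation can exclude them.
#'
#' @param raster a `raster_grid`.
#' @param plant one-row data frame (or list) with `x_m`, `y_m` and optionally
#'   `radius_m` and `plant_id`.
#' @param radius_m ROI radius override (default: the record's, else 0.20 m).
#' @return object of class `roi_pixels`: `values` (non-missing pixel values),
#'   `rows`, `cols` (full in-circle pixel indices), `patch` (bounding-box
#'   value matrix), `mask` (logical matrix: in circle and non-missing),
#'   `plant_id`.
#' @export
extract_roi <- function(raster, plant, radius_m = NULL) {
  r <- if (!is.null(radius_m)) radius_m
       else if (!is.null(plant$radius_m)) plant$radius_m else 0.20
  v <- raster$values
  cx <- plant$x_m; cy <- plant$y_m
  gsd <- raster$gsd
  # candidate bounding box in pixel indices
  c1 <- floor((cx - r - raster$xmin) / gsd) + 1L
  c2 <- floor((cx + r - raster$xmin) / gsd) + 1L
  r1 <- floor((raster$ymax - (cy + r)) / gsd) + 1L
  r2 <- floor((raster$ymax - (cy - r)) / gsd) + 1L
  c1 <- max(1L, c1); c2 <- min(ncol(v), c2)
  r1 <- max(1L, r1); r2 <- min(nrow(v), r2)
  if (c1 > c2 || r1 > r2) stop("extraction error: ROI fully outside raster")
  xs <- raster$xmin + ((c1:c2) - 0.5) * gsd
  ys <- raster$ymax - ((r1:r2) - 0.5) * gsd
  d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
  # pixel-centre rule with a tolerance so centres exactly on the circle
  # are kept regardless of floating-point representation
  incirc <- d2 <= r^2 * (1 + 1e-9)
  if (!any(incirc)) stop("extraction error: ROI fully outside raster")
  patch <- v[r1:r2, c1:c2, drop = FALSE]
  mask <- incirc & !is.na(patch)
  idx <- which(incirc, arr.ind = TRUE)
  vals <- patch[mask]
  structure(list(values = vals,
                 rows = r1 - 1L + idx[, 1], cols = c1 - 1L + idx[, 2],
                 patch = patch, mask = mask,
                 plant_id = if (!is.null(plant$plant_id)) plant$plant_id else NA_integer_),
            class = "roi_pixels")
}
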
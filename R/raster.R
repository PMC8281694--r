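#' Construct a georeferenced raster grid
#'
#' A `raster_grid` is a 2-D plane of values on a square-pixel grid with an
#' affine world mapping under the pixel-centre convention: the centre of pixel
#' (row i, col j), 1-based, sits at world coordinates
#' `x = xmin + (j - 0.5) * gsd`, `y = ymax - (i - 0.5) * gsd`.
#' Rows run north-to-south. Missing data is encoded as `NA`.
#'
#' @param values numeric matrix (rows = north to south).
#' @param xmin world x of the left (west) raster edge, metres.
#' @param ymax world y of the top (north) raster edge, metres.
#' @param gsd ground sampling distance, metres per pixel (> 0).
#' @param units free unit tag, e.g. `"m"`, `"reflectance"`, `"unitless"`.
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, xmin = 0, ymax = nrow(values) * gsd,
                        gsd = 1, units = "unitless") {
  if (!is.matrix(values)) stop("values must be a matrix")
  if (!is.numeric(gsd) || length(gsd) != 1 || gsd <= 0) stop("gsd must be a positive scalar")
  structure(list(values = values, xmin = xmin, ymax = ymax,
                 gsd = gsd, units = units),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("raster_grid %d x %d, gsd %g m, origin (%g, %g), units '%s', %d NA\n",
              nrow(x$values), ncol(x$values), x$gsd, x$xmin, x$ymax, x$units,
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' World coordinates of pixel centres
#'
#' @param g a `raster_grid`.
#' @return `pixel_x`: numeric vector of column-centre x coordinates;
#'   `pixel_y`: row-centre y coordinates (north to south).
#' @export
pixel_x <- function(g) g$xmin + (seq_len(ncol(g$values)) - 0.5) * g$gsd

#' @rdname pixel_x
#' @export
pixel_y <- function(g) g$ymax - (seq_len(nrow(g$values)) - 0.5) * g$gsd

#' Convert world coordinates to (row, col) pixel indices
#'
#' Points are mapped to the pixel whose cell contains them (1-based indices);
#' points outside the raster extent give NA.
#'
#' @param g a `raster_grid`.
#' @param x,y world coordinates (m).
#' @return a two-column integer matrix `(row, col)`.
#' @export
world_to_pixel <- function(g, x, y) {
  col <- floor((x - g$xmin) / g$gsd) + 1L
  row <- floor((g$ymax - y) / g$gsd) + 1L
  bad <- col < 1L | col > ncol(g$values) | row < 1L | row > nrow(g$values)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Check two rasters share shape and transform
#'
#' @param a,b `raster_grid` objects.
#' @param tol tolerance on transform components (m).
#' @return invisibly TRUE; raises an alignment error otherwise.
#' @export
check_aligned <- function(a, b, tol = 1e-9) {
  if (!identical(dim(a$values), dim(b$values)))
    stop("alignment error: raster shapes differ")
  if (abs(a$xmin - b$xmin) > tol || abs(a$ymax - b$ymax) > tol ||
      abs(a$gsd - b$gsd) > tol)
    stop("alignment error: raster transforms differ")
  invisible(TRUE)
}

# ---- ESRI ASCII grid I/O ----------------------------------------------------
# Plain-text interchange format: 6 header lines (ncols, nrows, xllcorner,
# yllcorner, cellsize, NODATA_value) then rows north-to-south. Values are
# written with 17 significant digits so write/read round-trips are exact.

#' Write a raster to an ESRI ASCII grid file
#'
#' @param g a `raster_grid`.
#' @param path output file path (conventionally `.asc`).
#' @param nodata numeric sentinel used on disk for `NA` pixels.
#' @return `path`, invisibly.
#' @export
write_map <- function(g, path, nodata = -9999) {
  v <- g$values
  nr <- nrow(v); nc <- ncol(v)
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.17g", g$xmin),
    sprintf("yllcorner %.17g", g$ymax - nr * g$gsd),
    sprintf("cellsize %.17g", g$gsd),
    sprintf("NODATA_value %.17g", nodata)
  )
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  # one text row per raster row, north first
  body <- apply(v, 1L, function(r) paste(formatC(r, format = "g", digits = 17), collapse = " "))
  writeLines(body, con)
  invisible(path)
}

#' Read an ESRI ASCII grid file
#'
#' @param path input `.asc` file.
#' @param units unit tag to attach (the format itself carries none).
#' @return a `raster_grid`.
#' @export
read_map <- function(path, units = "unitless") {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  key <- tolower(kv[, 1]); val <- as.numeric(kv[, 2])
  names(val) <- key
  nc <- as.integer(val[["ncols"]]); nr <- as.integer(val[["nrows"]])
  gsd <- val[["cellsize"]]
  body <- lines[-(1:6)]
  if (length(body) != nr) stop("corrupt ASCII grid: row count mismatch")
  v <- matrix(as.numeric(unlist(strsplit(trimws(body), "\\s+"))),
              nrow = nr, ncol = nc, byrow = TRUE)
  v[v == val[["nodata_value"]]] <- NA_real_
  raster_grid(v, xmin = val[["xllcorner"]],
              ymax = val[["yllcorner"]] + nr * gsd, gsd = gsd, units = units)
}

# ---- Scene stacks -----------------------------------------------------------

#' Construct a scene stack
#'
#' A `scene_stack` bundles, over an ordered axis of acquisition dates, the
#' per-date map registry (reflectance bands, surface/terrain models, and
#' derived plant-height / vegetation-index maps). Map names are lower case:
#' `blue, green, red, rededge, nir, dsm, dtm, ph, ndvi, gndvi, wdvi`.
#'
#' @param dates character vector of dates as `"MMDD"`, strictly increasing
#'   within one season.
#' @param year calendar year used to resolve dates to day-of-year.
#' @param maps named list (by date) of named lists (by map name) of
#'   `raster_grid` objects; may be empty and filled later with [set_map()].
#' @return an object of class `scene_stack`.
#' @export
scene_stack <- function(dates, year = 2020, maps = NULL) {
  doy <- date_to_doy(dates, year)
  if (any(diff(doy) <= 0)) stop("dates must be strictly increasing")
  if (is.null(maps)) maps <- stats::setNames(rep(list(list()), length(dates)), dates)
  structure(list(dates = dates, year = year, doy = doy, maps = maps),
            class = "scene_stack")
}

#' Day-of-year for MMDD date labels
#'
#' @param mmdd character vector `"MMDD"`.
#' @param year calendar year (affects leap years).
#' @return integer day-of-year values.
#' @export
date_to_doy <- function(mmdd, year = 2020) {
  d <- as.Date(sprintf("%d-%s-%s", year, substr(mmdd, 1, 2), substr(mmdd, 3, 4)))
  as.integer(format(d, "%j"))
}

#' Get or set one map of a scene
#'
#' @param scene a `scene_stack`.
#' @param date date label `"MMDD"` present in `scene$dates`.
#' @param name lower-case map name.
#' @param value a `raster_grid` (for `set_map`).
#' @return `get_map` returns the `raster_grid`; missing maps raise a
#'   missing-map error. `set_map` returns the modified scene.
#' @export
get_map <- function(scene, date, name) {
  if (!date %in% scene$dates) stop(sprintf("missing-map error: no date '%s' in scene", date))
  m <- scene$maps[[date]][[name]]
  if (is.null(m)) stop(sprintf("missing-map error: map '%s' absent for date %s", name, date))
  m
}

#' @rdname get_map
#' @export
set_map <- function(scene, date, name, value) {
  if (!inherits(value, "raster_grid")) stop("value must be a raster_grid")
  existing <- scene$maps[[date]]
  if (length(existing) > 0) check_aligned(existing[[1]], value)
  scene$maps[[date]][[name]] <- value
  scene
}

#' @export
print.scene_stack <- function(x, ...) {
  cat(sprintf("scene_stack: %d dates (%s..%s)\n", length(x$dates),
              x$dates[1], x$dates[length(x$dates)]))
  for (d in x$dates)
    cat(sprintf("  %s: %s\n", d, paste(names(x$maps[[d]]), collapse = ", ")))
  invisible(x)
}

#' Write a scene stack to a directory of ASCII grids
#'
#' Files follow the `<MMDD>_<map>.asc` naming convention with a
#' `scene.json` manifest recording dates, year and per-map units.
#'
#' @param scene a `scene_stack`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  units <- list()
  for (d in scene$dates) for (nm in names(scene$maps[[d]])) {
    g <- scene$maps[[d]][[nm]]
    write_map(g, file.path(dir, sprintf("%s_%s.asc", d, nm)))
    units[[nm]] <- g$units
  }
  jsonlite::write_json(list(dates = scene$dates, year = scene$year, units = units),
                       file.path(dir, "scene.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a scene stack from a directory of ASCII grids
#'
#' Expects the `<MMDD>_<map>.asc` convention written by [write_scene()]. All
#' rasters of one date must share shape and transform; `required` maps must be
#' present at every date.
#'
#' @param dir directory containing `.asc` files and optionally `scene.json`.
#' @param dates optional subset/order of dates; default all found.
#' @param required map names that must exist at each date (alignment/missing
#'   errors otherwise); default none.
#' @return a `scene_stack`.
#' @export
read_scene <- function(dir, dates = NULL, required = character()) {
  manifest <- file.path(dir, "scene.json")
  year <- 2020; units <- list()
  if (file.exists(manifest)) {
    man <- jsonlite::read_json(manifest, simplifyVector = TRUE)
    year <- man$year
    units <- as.list(man$units)
    if (is.null(dates)) dates <- man$dates
  }
  files <- list.files(dir, pattern = "^[0-9]{4}_[a-z]+\\.asc$")
  if (length(files) == 0) stop("no raster files found in scene directory")
  fdate <- substr(files, 1, 4)
  fname <- sub("\\.asc$", "", substr(files, 6, nchar(files)))
  if (is.null(dates)) dates <- sort(unique(fdate))
  scene <- scene_stack(dates, year = year)
  for (k in seq_along(files)) {
    if (!fdate[k] %in% dates) next
    u <- units[[fname[k]]]
    g <- read_map(file.path(dir, files[k]), units = if (is.null(u)) "unitless" else u)
    scene <- set_map(scene, fdate[k], fname[k], g)
  }
  for (d in dates) for (r in required)
    if (is.null(scene$maps[[d]][[r]]))
      stop(sprintf("missing-map error: required map '%s' absent for date %s", r, d))
  scene
}
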
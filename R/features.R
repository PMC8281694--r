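# Per-ROI feature engine: first-order statistics, gray-level quantization,
# GLCM construction, the 13 Haralick texture measures, growth rates, and
# assembly/normalization of the plant-by-variable feature table.

FIRST_ORDER_STATS <- c("AVE", "SD", "SKEW", "RANGE", "MAX")
GLCM_STATS <- c("SA", "Ent", "DE", "SE", "Var", "DV", "SV",
                "ASM", "IDM", "Con", "Cor", "MOC1", "MOC2")
FEATURE_MAPS <- c("PH", "NDVI", "GNDVI", "WDVI")

#' First-order ROI statistics
#'
#' Average, sample standard deviation (n-1 denominator), adjusted
#' Fisher-Pearson sample skewness, range and maximum of the ROI pixel values.
#' Skewness of a constant sample is 0 by convention.
#'
#' @param x numeric vector of ROI pixel values (or a `roi_pixels` object),
#'   length >= 2.
#' @return named numeric vector `AVE, SD, SKEW, RANGE, MAX`.
#' @export
first_order <- function(x) {
  if (inherits(x, "roi_pixels")) x <- x$values
  n <- length(x)
  if (n < 2) stop("insufficient-data error: need at least 2 pixel values")
  m <- mean(x)
  s <- stats::sd(x)
  m2 <- mean((x - m)^2)
  skew <- if (m2 == 0 || n < 3) 0 else {
    g1 <- mean((x - m)^3) / m2^1.5
    g1 * sqrt(n * (n - 1)) / (n - 2)
  }
  c(AVE = m, SD = s, SKEW = skew, RANGE = max(x) - min(x), MAX = max(x))
}

#' Quantize an ROI patch to N gray levels
#'
#' Linear binning of the valid-pixel value range into `n_levels` equal-width,
#' left-open/right-closed bins: the minimum maps to level 0, the maximum to
#' level `n_levels - 1`, and an interior bin edge belongs to the bin below it.
#' A constant patch maps entirely to level 0. The rule is invariant to affine
#' rescaling of the values.
#'
#' @param patch numeric matrix of pixel values.
#' @param mask logical matrix of valid pixels (default: non-missing entries).
#' @param n_levels number of gray levels N >= 2 (default 32).
#' @return integer matrix of levels in `[0, N-1]`, `NA` outside the mask.
#' @export
quantize <- function(patch, mask = NULL, n_levels = 32) {
  if (n_levels < 2) stop("n_levels must be >= 2")
  if (is.null(mask)) mask <- !is.na(patch)
  mask <- mask & !is.na(patch)
  if (!any(mask)) stop("quantize: no valid pixels")
  v <- patch[mask]
  rng <- max(v) - min(v)
  q <- matrix(NA_integer_, nrow(patch), ncol(patch))
  if (rng == 0) {
    q[mask] <- 0L
  } else {
    lev <- ceiling((v - min(v)) / rng * n_levels) - 1L
    q[mask] <- as.integer(pmax(lev, 0L))
  }
  q
}

#' Default GLCM displacement offsets
#'
#' Distance-1 offsets in the four Haralick directions 0, 45, 90 and 135
#' degrees, as `(row, col)` displacements on a north-up raster.
#'
#' @return list of integer pairs.
#' @export
glcm_offsets <- function() list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))

#' Build gray-level co-occurrence matrices
#'
#' For each displacement offset, counts co-occurring gray-level pairs over
#' all pixel positions p such that both p and p+offset are valid (inside the
#' ROI mask), optionally adds the transposed counts (symmetric accumulation),
#' and normalizes to sum 1. Offsets with no valid pair are dropped; if no
#' offset has any valid pair the GLCM is degenerate.
#'
#' @param q integer level matrix from [quantize()] (`NA` = invalid).
#' @param n_levels number of gray levels N.
#' @param offsets list of `(row, col)` displacements
#'   (default [glcm_offsets()]).
#' @param symmetric add transposed counts (default TRUE).
#' @return object of class `glcm_set`: `P` (list of N x N normalized
#'   matrices, one per retained offset), `N`, `offsets`.
#' @export
glcm <- function(q, n_levels = 32, offsets = glcm_offsets(), symmetric = TRUE) {
  nr <- nrow(q); nc <- ncol(q)
  N <- as.integer(n_levels)
  P <- list(); kept <- list()
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    r1 <- max(1L, 1L - dr); r2 <- min(nr, nr - dr)
    c1 <- max(1L, 1L - dc); c2 <- min(nc, nc - dc)
    if (r1 > r2 || c1 > c2) next
    a <- q[r1:r2, c1:c2, drop = FALSE]
    b <- q[(r1:r2) + dr, (c1:c2) + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    ai <- a[ok]; bi <- b[ok]
    counts <- matrix(tabulate(ai * N + bi + 1L, nbins = N * N), N, N, byrow = TRUE)
    if (symmetric) counts <- counts + t(counts)
    P[[length(P) + 1L]] <- counts / sum(counts)
    kept[[length(kept) + 1L]] <- off
  }
  if (length(P) == 0) stop("degenerate-GLCM error: no valid co-occurring pair")
  structure(list(P = P, N = N, offsets = kept), class = "glcm_set")
}

# cached index helpers per gray-level count
glcm_index_cache <- new.env(parent = emptyenv())
glcm_indices <- function(N) {
  key <- as.character(N)
  if (!is.null(glcm_index_cache[[key]])) return(glcm_index_cache[[key]])
  i <- matrix(0:(N - 1), N, N)            # row index, 0-based
  j <- t(i)
  out <- list(i = i, j = j, ipj = as.vector(i + j), imj = as.vector(abs(i - j)),
              w_idm = 1 / (1 + (i - j)^2), k_sum = 0:(2 * (N - 1)), k_dif = 0:(N - 1))
  glcm_index_cache[[key]] <- out
  out
}

xlogx <- function(p) ifelse(p > 0, p * log(p), 0)

# the 13 texture measures of a single normalized symmetric GLCM
glcm_features_one <- function(P, N) {
  ix <- glcm_indices(N)
  Px <- rowSums(P); Py <- colSums(P)
  lev <- 0:(N - 1)
  mu_x <- sum(lev * Px); mu_y <- sum(lev * Py)
  mu <- mu_x                       # symmetric GLCM: marginals coincide
  sd_x <- sqrt(sum((lev - mu_x)^2 * Px)); sd_y <- sqrt(sum((lev - mu_y)^2 * Py))
  Pxpy <- as.numeric(rowsum(as.vector(P), ix$ipj))       # k = 0..2(N-1)
  Pxmy <- as.numeric(rowsum(as.vector(P), ix$imj))       # k = 0..N-1
  SA <- sum(ix$k_sum * Pxpy)
  Ent <- -sum(xlogx(P))
  DE <- -sum(xlogx(Pxmy))
  SE <- -sum(xlogx(Pxpy))
  Var <- sum((ix$i - mu)^2 * P)
  mu_d <- sum(ix$k_dif * Pxmy)
  DV <- sum((ix$k_dif - mu_d)^2 * Pxmy)
  SV <- sum((ix$k_sum - SA)^2 * Pxpy)
  ASM <- sum(P^2)
  IDM <- sum(ix$w_idm * P)
  Con <- sum(ix$k_dif^2 * Pxmy)
  Cor <- if (sd_x * sd_y == 0) 0 else sum(P * (ix$i - mu_x) * (ix$j - mu_y)) / (sd_x * sd_y)
  HX <- -sum(xlogx(Px)); HY <- -sum(xlogx(Py))
  HXY <- Ent
  PxPy <- outer(Px, Py)
  HXY1 <- -sum(ifelse(P > 0, P * log(PxPy), 0))
  HXY2 <- -sum(xlogx(PxPy))
  MOC1 <- if (max(HX, HY) == 0) 0 else (HXY - HXY1) / max(HX, HY)
  MOC2 <- sqrt(max(0, 1 - exp(-2 * (HXY2 - HXY))))
  c(SA = SA, Ent = Ent, DE = DE, SE = SE, Var = Var, DV = DV, SV = SV,
    ASM = ASM, IDM = IDM, Con = Con, Cor = Cor, MOC1 = MOC1, MOC2 = MOC2)
}

#' Compute the 13 GLCM texture measures
#'
#' Sum average, entropy, difference/sum entropy, variance, difference/sum
#' variance, angular second moment, inverse difference moment, contrast,
#' correlation, and the two information measures of correlation. Each
#' direction's matrix is scored separately and the features are averaged over
#' directions. Natural logarithms throughout, with `0 log 0 = 0`. Degenerate
#' conventions: correlation is 0 when a marginal is constant; MOC1 is 0 when
#' `max(HX, HY) = 0`; the MOC2 argument is clamped at 0 before the square
#' root; sum variance is the positive dispersion of the gray-level-sum
#' distribution about the sum average.
#'
#' @param g a `glcm_set` from [glcm()].
#' @return named numeric vector of the 13 measures.
#' @export
glcm_features <- function(g) {
  feats <- vapply(g$P, glcm_features_one, numeric(13), N = g$N)
  rowMeans(feats)
}

# constant-patch convention, used when an ROI's GLCM is degenerate
constant_glcm_features <- function() {
  c(SA = 0, Ent = 0, DE = 0, SE = 0, Var = 0, DV = 0, SV = 0,
    ASM = 1, IDM = 1, Con = 0, Cor = 0, MOC1 = 0, MOC2 = 0)
}

#' Dynamic growth rates from a per-date series
#'
#' The change of a map's ROI average over two consecutive measurement days
#' divided by the interval in days: 10 dates yield 9 rates.
#'
#' @param ave numeric matrix (plants x dates) of per-date ROI averages, or a
#'   vector for one plant.
#' @param doy integer day-of-year per date, strictly increasing.
#' @return matrix (plants x intervals) of rates, per day.
#' @export
growth_rates <- function(ave, doy) {
  if (is.vector(ave)) ave <- matrix(ave, nrow = 1)
  if (ncol(ave) != length(doy)) stop("ave columns must match dates")
  dd <- diff(doy)
  if (any(dd == 0)) stop("interval error: duplicate dates")
  t(apply(ave, 1, diff)) / rep(dd, each = nrow(ave))
}

#' Feature-table column accounting
#'
#' @param n_maps,n_dates counts of maps and dates.
#' @param mode `"all"` (18 stats per map-date + per-map growth rates) or
#'   `"first_order"` (5 stats per map-date, no growth rates).
#' @return expected number of feature columns.
#' @export
feature_count <- function(n_maps, n_dates, mode = c("all", "first_order")) {
  mode <- match.arg(mode)
  n_maps <- as.integer(n_maps); n_dates <- as.integer(n_dates)
  if (mode == "all") n_maps * 18L * n_dates + n_maps * (n_dates - 1L)
  else n_maps * 5L * n_dates
}

#' Assemble the plant-by-variable feature table
#'
#' For every plant, date and map: the five first-order statistics and (in
#' `"all"` mode) the 13 GLCM texture measures of the circular ROI, plus (in
#' `"all"` mode) the per-map dynamic growth rates of the ROI average. Columns
#' are named `<MAP>_<STAT>_<MMDD>` and `<MAP>_GR_<MMDD1>-<MMDD2>`, ordered
#' map-major, then date, then statistic, with all growth-rate columns last.
#' With 10 dates and the default four maps the `"all"` table has
#' 4*18*10 + 4*9 = 756 columns.
#'
#' An ROI whose quantized patch admits no valid co-occurring pair receives
#' the constant-patch convention values (ASM 1, IDM 1, entropies/contrast 0).
#'
#' @param scene a `scene_stack` carrying `ph`, `ndvi`, `gndvi`, `wdvi` maps
#'   (see [derive_scene_maps()]).
#' @param plants plant-record data frame (see [plant_records()]).
#' @param maps feature maps to use, upper case (default
#'   `c("PH","NDVI","GNDVI","WDVI")`).
#' @param mode `"all"` or `"first_order"`.
#' @param n_levels GLCM gray levels (default 32).
#' @param dates optional subset of scene dates.
#' @return numeric matrix (plants x variables) with plant ids as row names
#'   and a `provenance` attribute (data frame: column, map, stat, date).
#' @export
assemble <- function(scene, plants, maps = FEATURE_MAPS,
                     mode = c("all", "first_order"), n_levels = 32,
                     dates = NULL) {
  mode <- match.arg(mode)
  if (is.null(dates)) dates <- scene$dates
  doy <- scene$doy[match(dates, scene$dates)]
  stats_used <- if (mode == "all") c(FIRST_ORDER_STATS, GLCM_STATS) else FIRST_ORDER_STATS
  np <- nrow(plants)
  blocks <- list()
  ave_store <- list()
  n_degenerate <- 0L
  for (mp in maps) {
    key <- tolower(mp)
    ave_mat <- matrix(NA_real_, np, length(dates))
    for (di in seq_along(dates)) {
      d <- dates[di]
      ras <- get_map(scene, d, key)
      block <- matrix(NA_real_, np, length(stats_used),
                      dimnames = list(NULL, stats_used))
      for (pi in seq_len(np)) {
        roi <- extract_roi(ras, plants[pi, ])
        fo <- first_order(roi$values)
        block[pi, FIRST_ORDER_STATS] <- fo
        if (mode == "all") {
          q <- quantize(roi$patch, roi$mask, n_levels = n_levels)
          gf <- tryCatch(glcm_features(glcm(q, n_levels = n_levels)),
                         error = function(e) {
                           n_degenerate <<- n_degenerate + 1L
                           constant_glcm_features()
                         })
          block[pi, GLCM_STATS] <- gf
        }
      }
      colnames(block) <- sprintf("%s_%s_%s", mp, stats_used, d)
      blocks[[length(blocks) + 1L]] <- block
      ave_mat[, di] <- block[, sprintf("%s_AVE_%s", mp, d)]
    }
    ave_store[[mp]] <- ave_mat
  }
  if (mode == "all" && length(dates) >= 2) {
    for (mp in maps) {
      gr <- growth_rates(ave_store[[mp]], doy)
      colnames(gr) <- sprintf("%s_GR_%s-%s", mp, dates[-length(dates)], dates[-1])
      blocks[[length(blocks) + 1L]] <- gr
    }
  }
  if (n_degenerate > 0)
    message(sprintf("assemble: %d degenerate GLCM(s) set to constant-patch values",
                    n_degenerate))
  X <- do.call(cbind, blocks)
  rownames(X) <- plants$plant_id
  cn <- colnames(X)
  prov <- data.frame(column = cn,
                     map = sub("^([A-Z]+)_.*$", "\\1", cn),
                     stat = sub("^[A-Z]+_([A-Za-z0-9]+)_.*$", "\\1", cn),
                     date = sub("^.*_", "", cn))
  attr(X, "provenance") <- prov
  X
}

#' Normalize a feature table
#'
#' Centres every column to mean 0 and scales to sample standard deviation 1.
#' Zero-variance columns are set to 0 and flagged. The `center` and `scale`
#' attributes allow exact de-normalization.
#'
#' @param X numeric feature matrix (plants x variables), >= 2 rows.
#' @return the normalized matrix with attributes `center`, `scale`
#'   (pre-scaling SDs; 1 recorded for constant columns) and `constant`
#'   (logical flag per column).
#' @export
normalize_features <- function(X) {
  if (nrow(X) < 2) stop("need at least 2 rows to normalize")
  ctr <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  const <- sds == 0 | !is.finite(sds)
  sds[const] <- 1
  Z <- sweep(sweep(X, 2, ctr), 2, sds, "/")
  Z[, const] <- 0
  attr(Z, "center") <- ctr
  attr(Z, "scale") <- sds
  attr(Z, "constant") <- const
  attr(Z, "provenance") <- attr(X, "provenance")
  Z
}

#' Invert [normalize_features()]
#'
#' @param Z normalized matrix carrying `center` and `scale` attributes.
#' @return the original-scale matrix (constant columns restored to their
#'   centre value).
#' @export
denormalize_features <- function(Z) {
  sweep(sweep(Z, 2, attr(Z, "scale"), "*"), 2, attr(Z, "center"), "+")
}
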
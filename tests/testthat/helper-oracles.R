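# Independent brute-force oracles, written as literal formula transcriptions,
# deliberately sharing no code with the package implementation.

# co-occurrence counts by explicit enumeration of all pixel pairs
glcm_oracle_matrix <- function(q, N, offset, symmetric = TRUE) {
  P <- matrix(0, N, N)
  nr <- nrow(q); nc <- ncol(q)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    r2 <- r + offset[1]; c2 <- cc + offset[2]
    if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
        !is.na(q[r, cc]) && !is.na(q[r2, c2])) {
      P[q[r, cc] + 1, q[r2, c2] + 1] <- P[q[r, cc] + 1, q[r2, c2] + 1] + 1
      if (symmetric) P[q[r2, c2] + 1, q[r, cc] + 1] <- P[q[r2, c2] + 1, q[r, cc] + 1] + 1
    }
  }
  if (sum(P) == 0) stop("oracle: no pairs")
  P / sum(P)
}

# the 13 texture measures as literal sums (loops, no vectorized reuse)
glcm_oracle_features <- function(P) {
  N <- nrow(P)
  lg <- function(v) if (v > 0) log(v) else 0
  Px <- rowSums(P); Py <- colSums(P)
  Pxpy <- numeric(2 * N - 1)   # k = 0 .. 2(N-1)
  Pxmy <- numeric(N)           # k = 0 .. N-1
  for (i in 1:N) for (j in 1:N) {
    Pxpy[(i - 1) + (j - 1) + 1] <- Pxpy[(i - 1) + (j - 1) + 1] + P[i, j]
    Pxmy[abs(i - j) + 1] <- Pxmy[abs(i - j) + 1] + P[i, j]
  }
  mu_x <- sum((0:(N - 1)) * Px); mu_y <- sum((0:(N - 1)) * Py)
  sd_x <- sqrt(sum(((0:(N - 1)) - mu_x)^2 * Px))
  sd_y <- sqrt(sum(((0:(N - 1)) - mu_y)^2 * Py))
  SA <- sum((0:(2 * (N - 1))) * Pxpy)
  Ent <- 0; Var <- 0; ASM <- 0; IDM <- 0; Cor <- 0
  HXY1 <- 0
  for (i in 1:N) for (j in 1:N) {
    Ent <- Ent - P[i, j] * lg(P[i, j])
    Var <- Var + ((i - 1) - mu_x)^2 * P[i, j]
    ASM <- ASM + P[i, j]^2
    IDM <- IDM + P[i, j] / (1 + ((i - 1) - (j - 1))^2)
    if (sd_x * sd_y > 0)
      Cor <- Cor + P[i, j] * ((i - 1) - mu_x) * ((j - 1) - mu_y) / (sd_x * sd_y)
    if (P[i, j] > 0) HXY1 <- HXY1 - P[i, j] * lg(Px[i] * Py[j])
  }
  DE <- -sum(sapply(seq_along(Pxmy), function(k) Pxmy[k] * lg(Pxmy[k])))
  SE <- -sum(sapply(seq_along(Pxpy), function(k) Pxpy[k] * lg(Pxpy[k])))
  mu_d <- sum((0:(N - 1)) * Pxmy)
  DV <- sum(((0:(N - 1)) - mu_d)^2 * Pxmy)
  SV <- sum(((0:(2 * (N - 1))) - SA)^2 * Pxpy)
  Con <- sum((0:(N - 1))^2 * Pxmy)
  HX <- -sum(sapply(1:N, function(i) Px[i] * lg(Px[i])))
  HY <- -sum(sapply(1:N, function(j) Py[j] * lg(Py[j])))
  HXY2 <- 0
  for (i in 1:N) for (j in 1:N) HXY2 <- HXY2 - Px[i] * Py[j] * lg(Px[i] * Py[j])
  MOC1 <- if (max(HX, HY) == 0) 0 else (Ent - HXY1) / max(HX, HY)
  MOC2 <- sqrt(max(0, 1 - exp(-2 * (HXY2 - Ent))))
  c(SA = SA, Ent = Ent, DE = DE, SE = SE, Var = Var, DV = DV, SV = SV,
    ASM = ASM, IDM = IDM, Con = Con, Cor = Cor, MOC1 = MOC1, MOC2 = MOC2)
}

# number of lattice points (pixel centres) within a disc, by enumeration
disc_lattice_count <- function(radius_px) {
  n <- 0L
  r <- ceiling(radius_px)
  for (i in -r:r) for (j in -r:r)
    if (i * i + j * j <= radius_px^2) n <- n + 1L
  n
}

# soft-thresholding solution of the lasso on an orthonormal design
# (columns with X'X / n = I): beta_j = sign(z_j) max(|z_j| - lambda, 0),
# z_j = x_j' y / n
soft_threshold_lasso <- function(X, y, lambda) {
  z <- as.numeric(crossprod(X, y)) / nrow(X)
  sign(z) * pmax(abs(z) - lambda, 0)
}
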
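test_that("first-order statistics match closed forms", {
  fo <- first_order(c(1, 2, 3))
  expect_equal(unname(fo), c(2, 1, 0, 2, 3))
  fo5 <- first_order(c(5, 5, 5))
  expect_equal(unname(fo5[c("SD", "SKEW", "RANGE")]), c(0, 0, 0))
  expect_error(first_order(3), "insufficient-data")
})

test_that("sample skewness agrees with the independent e1071 implementation", {
  set.seed(21)
  for (i in 1:5) {
    x <- rgamma(60, shape = 2)
    expect_equal(unname(first_order(x)["SKEW"]),
                 e1071::skewness(x, type = 2), tolerance = 1e-12)
  }
})

test_that("seeded Gaussian draws recover their moments", {
  set.seed(99)
  x <- rnorm(1000, 0.3, 0.05)
  fo <- first_order(x)
  expect_lt(abs(fo[["AVE"]] - 0.3), 3 * 0.05 / sqrt(1000))
  expect_lt(abs(fo[["SD"]] - 0.05), 3 * 0.05 / sqrt(2 * 999))
})

test_that("quantization follows the right-closed binning rule", {
  q <- quantize(matrix(c(0, 0.5, 1), 1, 3), n_levels = 2)
  expect_identical(as.integer(q), c(0L, 0L, 1L))
  expect_true(all(quantize(matrix(5, 3, 3), n_levels = 8) == 0L))
  # max always maps to N-1, min to 0
  set.seed(4)
  m <- matrix(runif(64), 8, 8)
  q8 <- quantize(m, n_levels = 8)
  expect_identical(q8[which.max(m)], 7L)
  expect_identical(q8[which.min(m)], 0L)
})

test_that("quantization is invariant to affine rescaling", {
  set.seed(12)
  for (i in 1:10) {
    m <- matrix(rnorm(100), 10, 10)
    a <- runif(1, 0.1, 5); b <- rnorm(1)
    expect_identical(quantize(m, n_levels = 16), quantize(a * m + b, n_levels = 16))
  }
})

test_that("GLCM of the two-row patch matches hand enumeration", {
  q <- matrix(c(0L, 1L, 0L, 1L), 2, 2)     # [[0,0],[1,1]] rows
  g <- glcm(q, n_levels = 2, offsets = list(c(0L, 1L)))
  expect_equal(g$P[[1]], matrix(c(0.5, 0, 0, 0.5), 2, 2))
  f <- glcm_features(g)
  expect_equal(f[["ASM"]], 0.5)
  expect_equal(f[["Ent"]], log(2))
  expect_equal(f[["Con"]], 0)
  expect_equal(f[["IDM"]], 1)
  expect_equal(f[["Cor"]], 1)
})

test_that("constant patches give the degenerate texture conventions", {
  q <- matrix(0L, 5, 5)
  f <- glcm_features(glcm(q, n_levels = 8))
  expect_equal(f[["ASM"]], 1)
  expect_equal(f[["Ent"]], 0)
  expect_equal(f[["Con"]], 0)
  expect_equal(f[["IDM"]], 1)
  expect_equal(f[["DV"]], 0)
  # a single valid pixel has no pairs at all
  q1 <- matrix(NA_integer_, 3, 3); q1[2, 2] <- 0L
  expect_error(glcm(q1, n_levels = 4), "degenerate-GLCM")
})

test_that("GLCM invariants hold and features equal the literal-formula oracle", {
  set.seed(31)
  n_checked <- 0
  for (i in 1:100) {
    nr <- sample(4:9, 1); nc <- sample(4:9, 1)
    N <- sample(c(4L, 6L, 8L, 16L), 1)
    q <- matrix(sample(0:(N - 1), nr * nc, replace = TRUE), nr, nc)
    if (i %% 3 == 0) q[sample(length(q), ceiling(length(q) / 5))] <- NA  # masked pixels
    g <- glcm(q, n_levels = N)
    for (k in seq_along(g$P)) {
      P <- g$P[[k]]
      expect_equal(sum(P), 1, tolerance = 1e-12)
      expect_equal(P, t(P), tolerance = 1e-12)
      expect_true(all(P >= 0))
      # oracle equality per direction
      Po <- glcm_oracle_matrix(q, N, g$offsets[[k]])
      expect_equal(P, Po, tolerance = 1e-12)
      n_checked <- n_checked + 1
    }
    f <- glcm_features(g)
    fo <- rowMeans(vapply(g$P, glcm_oracle_features, numeric(13)))
    expect_equal(f, fo, tolerance = 1e-10)
  }
  expect_gte(n_checked, 100)
})

test_that("texture features order heterogeneity as expected", {
  checker <- matrix(rep_len(c(0L, 1L), 64), 8, 8)
  const <- matrix(0L, 8, 8)
  fc <- glcm_features(glcm(checker, n_levels = 2))
  f0 <- glcm_features(glcm(const, n_levels = 2))
  expect_lt(fc[["ASM"]], f0[["ASM"]])
  expect_gt(fc[["Ent"]], f0[["Ent"]])
  # IDM = 1 iff only diagonal cells occupied
  expect_equal(f0[["IDM"]], 1)
  expect_lt(fc[["IDM"]], 1)
})

test_that("growth rates divide consecutive changes by the day interval", {
  r <- growth_rates(c(0.20, 0.32), c(100, 106))
  expect_equal(as.numeric(r), 0.02)
  expect_equal(as.numeric(growth_rates(rep(1, 5), c(1, 3, 6, 10, 15))), rep(0, 4))
  r10 <- growth_rates(matrix(rnorm(20), 2, 10), seq(10, 100, by = 10))
  expect_identical(dim(r10), c(2L, 9L))
  expect_error(growth_rates(c(1, 2), c(5, 5)), "interval error")
})

test_that("feature accounting follows |maps| x 18 x |dates| + |maps| x (|dates|-1)", {
  expect_identical(feature_count(4, 10, "all"), 756L)
  expect_identical(feature_count(1, 10, "all"), 189L)
  expect_identical(feature_count(4, 10, "first_order"), 200L)
  for (m in 1:4) for (d in 2:10)
    expect_identical(feature_count(m, d, "all"), m * 18L * d + m * (d - 1L))
})

test_that("assembled tables have the documented shape and deterministic order", {
  scene <- tiny_scene()
  rec <- tiny_records()
  X <- assemble(scene, rec, dates = scene$dates[1:3])
  expect_identical(dim(X), c(nrow(rec), feature_count(4, 3, "all")))
  X_ph <- assemble(scene, rec, maps = "PH", dates = scene$dates[1:3])
  expect_identical(ncol(X_ph), feature_count(1, 3, "all"))
  Xf <- assemble(scene, rec, mode = "first_order", dates = scene$dates[1:3])
  expect_identical(ncol(Xf), feature_count(4, 3, "first_order"))
  # PH block columns appear first and growth rates last
  expect_match(colnames(X)[1], "^PH_AVE_")
  expect_match(colnames(X)[ncol(X)], "^WDVI_GR_")
  expect_false(anyDuplicated(colnames(X)) > 0)
  # rerun is identical
  X2 <- assemble(scene, rec, dates = scene$dates[1:3])
  expect_identical(X, X2)
})

test_that("normalization centres, scales, flags constants and inverts", {
  set.seed(8)
  X <- cbind(a = rnorm(40, 5, 2), b = runif(40), c = rep(3, 40))
  Z <- normalize_features(X)
  expect_lt(max(abs(colMeans(Z))), 1e-12)
  expect_equal(unname(apply(Z[, 1:2], 2, sd)), c(1, 1), tolerance = 1e-12)
  expect_true(all(Z[, "c"] == 0))
  expect_identical(unname(attr(Z, "constant")), c(FALSE, FALSE, TRUE))
  expect_equal(denormalize_features(Z), X, tolerance = 1e-12,
               ignore_attr = TRUE)
})
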
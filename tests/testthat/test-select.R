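test_that("boruta confirms a strong signal and ranks it first", {
  d <- make_design(150, 21, seed = 301, beta = c(3, rep(0, 20)), noise = 0.5)
  res <- boruta_select(d$X, d$y, seed = 17)
  expect_identical(unname(res$decision["V01"]), "confirmed")
  expect_identical(res$top_k[1], "V01")
})

test_that("boruta keeps null false positives at the test level", {
  confirmed <- 0
  for (s in 1:3) {
    d <- make_design(100, 40, seed = 310 + s)     # y independent of X
    res <- boruta_select(d$X, d$y, max_runs = 25, seed = s)
    confirmed <- confirmed + sum(res$decision == "confirmed")
  }
  expect_lte(confirmed, 2)   # alpha 0.01 with Bonferroni: ~0 expected
})

test_that("duplicated causal columns both score highly in boruta", {
  d <- make_design(150, 10, seed = 305, beta = c(2, rep(0, 9)), noise = 0.5)
  X2 <- cbind(d$X, V01dup = d$X[, "V01"])
  res <- boruta_select(X2, d$y, seed = 3)
  ranks <- rank(-res$importances)
  expect_lte(max(ranks[c("V01", "V01dup")]), 3)
})

test_that("permutation importance separates signal from noise", {
  set.seed(77)
  X <- matrix(rnorm(120 * 8), 120, 8); colnames(X) <- sprintf("V%02d", 1:8)
  y <- X[, 1]                              # noiseless
  res <- permimp_select(X, y, seed = 9)
  expect_identical(res$top_k[1], "V01")
  # permuting the causal column strictly increases the loss; permuting the
  # pure-noise columns moves it far less
  expect_gt(res$importances["V01"], 0)
  expect_gt(res$importances["V01"], 3 * max(abs(res$importances[-1])))
  # equal coefficients -> comparable importances
  d <- make_design(200, 6, seed = 401, beta = c(1, 1, 0, 0, 0, 0), noise = 0.3)
  r2 <- permimp_select(d$X, d$y, n_permutations = 5, seed = 11)
  ratio <- r2$importances["V01"] / r2$importances["V02"]
  expect_gt(ratio, 0.5); expect_lt(ratio, 2)
  # permutation count does not change the top variable on strong signal
  rA <- permimp_select(d$X, d$y, n_permutations = 1, seed = 5)
  rB <- permimp_select(d$X, d$y, n_permutations = 10, seed = 5)
  expect_identical(sort(rA$top_k[1:2]), sort(rB$top_k[1:2]))
})

test_that("the genetic algorithm concentrates on the causal column", {
  d <- make_design(120, 30, seed = 501, beta = c(2, rep(0, 29)), noise = 0.4)
  res <- ga_select(d$X, d$y, population = 30, generations = 30, seed = 23)
  expect_gt(res$importances["V01"], 0.8)
  expect_true("V01" %in% res$top_k)
  # determinism
  res2 <- ga_select(d$X, d$y, population = 30, generations = 30, seed = 23)
  expect_identical(res$importances, res2$importances)
  expect_error(ga_select(d$X, d$y, population = 2, seed = 1),
               "configuration error")
})

test_that("without crossover and mutation the GA only reshuffles existing chromosomes", {
  d <- make_design(60, 12, seed = 502)
  res <- ga_select(d$X, d$y, population = 12, generations = 6,
                   crossover_p = 0, mutation_p = 0, init_p = 0.5, seed = 31)
  # selection frequencies can only move toward 0/1 mixtures of initial rows;
  # at minimum the result is deterministic and well-formed
  expect_true(all(res$importances >= 0 & res$importances <= 1))
  res2 <- ga_select(d$X, d$y, population = 12, generations = 6,
                    crossover_p = 0, mutation_p = 0, init_p = 0.5, seed = 31)
  expect_identical(res$importances, res2$importances)
})

test_that("lasso matches the soft-thresholding closed form on orthonormal designs", {
  set.seed(61)
  n <- 100; p <- 8
  # centred columns orthonormalized so that X'X / n = I exactly
  Q <- qr.Q(qr(scale(matrix(rnorm(n * p), n, p), scale = FALSE))) * sqrt(n)
  colnames(Q) <- sprintf("V%02d", 1:p)
  y <- 5 * Q[, 1] + rnorm(n, 0, 0.5)
  res <- lasso_select(Q, y, seed = 7)
  beta_oracle <- soft_threshold_lasso(Q, y - mean(y), res$lambda_min)
  expect_equal(unname(res$importances), abs(beta_oracle), tolerance = 1e-4)
  expect_identical(res$top_k[1], "V01")
})

test_that("lasso penalty limits behave correctly", {
  d <- make_design(80, 5, seed = 604, beta = c(1, -2, 0.5, 0, 0), noise = 0.2)
  # enormous penalty: everything zero
  expect_warning(res_inf <- lasso_select(d$X, d$y, lambda_grid = c(1e4, 9e3),
                                         seed = 2),
                 "all coefficients zero")
  expect_length(res_inf$top_k, 0)
  # vanishing penalty with n > p: OLS limit
  res0 <- lasso_select(d$X, d$y, lambda_grid = c(1e-7, 5e-8), seed = 2)
  ols <- coef(lm(d$y ~ d$X))[-1]
  expect_equal(unname(res0$importances), unname(abs(ols)), tolerance = 1e-3)
})

test_that("RFE keeps causal variables to the end and respects the optimal size", {
  d <- make_design(150, 33, seed = 701, beta = c(2, 2, 2, rep(0, 30)), noise = 0.5)
  res <- rfe_select(d$X, d$y, seed = 13)
  expect_true(all(c("V01", "V02", "V03") %in% res$top_k))
  # top_k length is capped by the OOB-optimal subset size
  expect_identical(length(res$top_k), min(5L, res$best_size))
  # elimination order covers every candidate exactly once
  expect_setequal(names(res$importances), colnames(d$X))
})

test_that("selection is invariant to column order up to the tie-break", {
  d <- make_design(120, 12, seed = 801, beta = c(2, 1, rep(0, 10)), noise = 0.3)
  perm <- sample(ncol(d$X))
  r1 <- lasso_select(d$X, d$y, seed = 5)
  r2 <- lasso_select(d$X[, perm], d$y, seed = 5)
  expect_setequal(r1$top_k, r2$top_k)
  b1 <- boruta_select(d$X, d$y, seed = 5)
  b2 <- boruta_select(d$X[, perm], d$y, seed = 5)
  expect_identical(b1$top_k[1], b2$top_k[1])
})

test_that("averaging importances respects ties, repeats and candidate checks", {
  mk <- function(imp) {
    structure(list(method = "lasso", importances = imp,
                   decision = setNames(rep("n/a", length(imp)), names(imp)),
                   top_k = names(sort(-imp))[1:2], seed = 1L),
              class = "selection_result")
  }
  one <- mk(c(a = 1, b = 2, c = 3))
  avg1 <- average_and_rank(list(one), k = 2)
  expect_identical(avg1$importances, one$importances)
  expect_identical(avg1$top_k, one$top_k)
  # swapped ranks with equal means: lexicographic, deterministic
  two <- average_and_rank(list(mk(c(a = 2, b = 1, c = 0)),
                               mk(c(a = 1, b = 2, c = 0))), k = 2)
  expect_identical(two$top_k, c("a", "b"))
  expect_error(average_and_rank(list(one, mk(c(x = 1, y = 2, z = 3)))),
               "aggregation error")
})

test_that("every method is reproducible under a fixed seed", {
  d <- make_design(100, 15, seed = 901, beta = c(1.5, rep(0, 14)), noise = 0.4)
  for (m in c("boruta", "permimp", "ga", "lasso", "rfe")) {
    r1 <- run_selection(d$X, d$y, method = m, repeats = 2, seed = 44)
    r2 <- run_selection(d$X, d$y, method = m, repeats = 2, seed = 44)
    expect_identical(r1$importances, r2$importances)
    expect_identical(r1$top_k, r2$top_k)
  }
})
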
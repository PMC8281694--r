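# Yield prediction: train/test split, hyperparameter tuning for random
# forest / ridge / SVM, held-out evaluation by R-squared and relative RMSE,
# and the full trait x variable-set x model evaluation grid.

#' Seeded train/test split
#'
#' Uniform random partition into `floor(train_fraction * n)` training rows
#' and the remainder for testing; disjoint and exhaustive.
#'
#' @param n number of rows (>= 10).
#' @param train_fraction default 0.8.
#' @param seed integer seed.
#' @return list `train`, `test` of sorted row indices.
#' @export
split_data <- function(n, train_fraction = 0.8, seed = 1L) {
  if (n < 10) stop("need at least 10 rows to split")
  if (train_fraction <= 0 || train_fraction >= 1) stop("train_fraction in (0,1)")
  set.seed(seed)
  tr <- sort(sample.int(n, floor(train_fraction * n)))
  list(train = tr, test = setdiff(seq_len(n), tr))
}

#' Tune and fit one prediction model
#'
#' * `rf` — random forest (500 trees); the variables-per-split parameter is
#'   tuned by out-of-bag error over a doubling/halving ladder around p/3
#'   (`randomForest::tuneRF`).
#' * `ridge` — L2-penalized linear regression; the penalty is chosen by
#'   k-fold cross-validation over a log-spaced grid (`glmnet`, alpha 0).
#' * `svm` — radial-basis epsilon-regression; cost, gamma and epsilon are
#'   chosen by k-fold cross-validated grid search (`e1071::tune.svm`).
#'
#' The returned model is refit on the full training set.
#'
#' @param kind `"rf"`, `"ridge"` or `"svm"`.
#' @param X_train,y_train training data.
#' @param cv_folds folds for ridge/SVM tuning (default 10).
#' @param seed integer seed.
#' @param grids optional named list overriding the default tuning grids
#'   (`ridge_lambda`, `svm_cost`, `svm_gamma`, `svm_epsilon`).
#' @return object of class `yield_model`: `kind`, `fit`, `tuned`.
#' @export
tune_fit <- function(kind = c("rf", "ridge", "svm"), X_train, y_train,
                     cv_folds = 10, seed = 1L, grids = list()) {
  kind <- match.arg(kind)
  p <- ncol(X_train)
  if (is.null(p) || p == 0) stop("configuration error: no predictor columns")
  set.seed(seed)
  if (kind == "rf") {
    mtry <- tryCatch({
      tr <- utils::capture.output(
        res <- suppressWarnings(
          randomForest::tuneRF(as.data.frame(X_train), y_train,
                               ntreeTry = 200, stepFactor = 2,
                               improve = 0.01, trace = FALSE, plot = FALSE)))
      res[which.min(res[, 2]), 1]
    }, error = function(e) max(1L, floor(p / 3)))
    mtry <- min(max(1L, as.integer(mtry)), p)   # the tuning ladder can probe past p
    fit <- randomForest::randomForest(as.data.frame(X_train), y_train,
                                      ntree = 500, mtry = mtry)
    tuned <- list(mtry = as.integer(mtry), ntree = 500L)
  } else if (kind == "ridge") {
    lambda <- grids$ridge_lambda
    if (is.null(lambda)) lambda <- 10^seq(3, -6, length.out = 80)
    fold_id <- sample(rep(seq_len(cv_folds), length.out = nrow(X_train)))
    cv <- glmnet::cv.glmnet(X_train, y_train, alpha = 0, lambda = lambda,
                            foldid = fold_id)
    fit <- cv
    tuned <- list(lambda = cv$lambda.min)
  } else {
    cost <- grids$svm_cost; if (is.null(cost)) cost <- 2^(0:4)
    gamma <- grids$svm_gamma; if (is.null(gamma)) gamma <- 2^(-2:1) / p
    epsilon <- grids$svm_epsilon; if (is.null(epsilon)) epsilon <- c(0.05, 0.1)
    tn <- e1071::tune.svm(x = as.matrix(X_train), y = y_train,
                          cost = cost, gamma = gamma, epsilon = epsilon,
                          kernel = "radial",
                          tunecontrol = e1071::tune.control(cross = cv_folds))
    fit <- tn$best.model
    tuned <- as.list(tn$best.parameters)
  }
  structure(list(kind = kind, fit = fit, tuned = tuned), class = "yield_model")
}

#' Predict from a tuned yield model
#'
#' @param model a `yield_model` from [tune_fit()].
#' @param X new data (matrix with the training columns).
#' @return numeric predictions.
#' @export
predict_yield <- function(model, X) {
  switch(model$kind,
    rf = as.numeric(stats::predict(model$fit, as.data.frame(X))),
    ridge = as.numeric(stats::predict(model$fit, newx = as.matrix(X), s = "lambda.min")),
    svm = as.numeric(stats::predict(model$fit, as.matrix(X))))
}

#' Held-out evaluation metrics
#'
#' `r2 = 1 - SS_res / SS_tot` on the test set (the squared Pearson
#' correlation is reported alongside as `r2_pearson`), and
#' `rrmse_pct = 100 * RMSE / mean(observed)`.
#'
#' @param observed,predicted paired numeric vectors.
#' @return list of class `prediction_eval`: `r2`, `r2_pearson`, `rmse`,
#'   `rrmse_pct`, `n`, `observed`, `predicted`.
#' @export
evaluate_predictions <- function(observed, predicted) {
  if (length(observed) == 0) stop("empty test set")
  if (length(observed) != length(predicted)) stop("length mismatch")
  mo <- mean(observed)
  if (mo == 0) stop("rRMSE undefined: mean observed value is zero")
  ssr <- sum((observed - predicted)^2)
  sst <- sum((observed - mo)^2)
  rmse <- sqrt(mean((observed - predicted)^2))
  r2p <- if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) 0
         else stats::cor(observed, predicted)^2
  structure(list(r2 = 1 - ssr / sst, r2_pearson = r2p, rmse = rmse,
                 rrmse_pct = 100 * rmse / mo, n = length(observed),
                 observed = observed, predicted = predicted),
            class = "prediction_eval")
}

#' @export
print.prediction_eval <- function(x, ...) {
  cat(sprintf("prediction_eval: n=%d, R2=%.3f, rRMSE=%.1f%%\n", x$n, x$r2, x$rrmse_pct))
  invisible(x)
}

#' Evaluate a model kind on one variable set
#'
#' Splits, tunes and fits on the training part, and evaluates on the
#' held-out part. Test rows never influence tuning or fitting.
#'
#' @param X feature matrix (original scale).
#' @param y trait vector.
#' @param vars column names to use.
#' @param kind model kind (see [tune_fit()]).
#' @param train_fraction,cv_folds,seed split and tuning controls.
#' @return a `prediction_eval` with the fitted model attached as
#'   `$model`.
#' @export
fit_and_evaluate <- function(X, y, vars, kind, train_fraction = 0.8,
                             cv_folds = 10, seed = 1L) {
  miss <- setdiff(vars, colnames(X))
  if (length(miss) > 0)
    stop(sprintf("input error: unknown variables: %s", paste(miss, collapse = ", ")))
  sp <- split_data(length(y), train_fraction, seed = seed)
  Xs <- X[, vars, drop = FALSE]
  model <- tune_fit(kind, Xs[sp$train, , drop = FALSE], y[sp$train],
                    cv_folds = cv_folds, seed = sub_seed(seed, 1L))
  ev <- evaluate_predictions(y[sp$test], predict_yield(model, Xs[sp$test, , drop = FALSE]))
  ev$model <- model
  ev$split <- sp
  ev
}

#' Repeated-split evaluation dispersion
#'
#' Repeats the split/tune/fit/evaluate cycle over independent seeded 80/20
#' partitions and summarises the dispersion of the held-out metrics. The
#' single-split metrics of [fit_and_evaluate()] remain the headline numbers;
#' this reports how much they move with the partition.
#'
#' @param X,y,vars,kind as in [fit_and_evaluate()].
#' @param repeats number of independent splits (default 20).
#' @param train_fraction,cv_folds,seed controls.
#' @return list: `r2` and `rrmse_pct` (vectors over repeats), plus
#'   `r2_mean`, `r2_sd`, `rrmse_mean`, `rrmse_sd`.
#' @export
repeated_split_eval <- function(X, y, vars, kind, repeats = 20,
                                train_fraction = 0.8, cv_folds = 10,
                                seed = 1L) {
  evs <- lapply(seq_len(repeats), function(r)
    fit_and_evaluate(X, y, vars, kind, train_fraction, cv_folds,
                     seed = sub_seed(seed, r)))
  r2 <- vapply(evs, function(e) e$r2, numeric(1))
  rr <- vapply(evs, function(e) e$rrmse_pct, numeric(1))
  list(r2 = r2, rrmse_pct = rr,
       r2_mean = mean(r2), r2_sd = stats::sd(r2),
       rrmse_mean = mean(rr), rrmse_sd = stats::sd(rr))
}

#' Full evaluation grid over traits, variable sets and models
#'
#' For every trait, selection set and model kind: split, tune, fit and
#' evaluate. The same seeded split is used for every model of one trait so
#' models are compared on identical held-out plants.
#'
#' @param X feature matrix (original scale).
#' @param yields data frame with one column per trait.
#' @param selections nested named list: `selections[[trait]][[set_name]]` is
#'   a character vector of variable names.
#' @param models model kinds (default all three).
#' @param traits traits to evaluate (default: names of `selections`).
#' @param train_fraction,cv_folds controls (defaults 0.8, 10).
#' @param seed master seed.
#' @return list: `grid` (data frame trait, set, model, r2, r2_pearson,
#'   rrmse_pct, n_vars, n_test), `evals` (nested list of `prediction_eval`).
#' @export
run_matrix <- function(X, yields, selections, models = c("rf", "ridge", "svm"),
                       traits = names(selections), train_fraction = 0.8,
                       cv_folds = 10, seed = 1L) {
  rows <- list(); evals <- list()
  for (ti in seq_along(traits)) {
    trait <- traits[ti]
    if (!trait %in% names(yields)) stop(sprintf("input error: trait '%s' missing", trait))
    y <- yields[[trait]]
    for (set_name in names(selections[[trait]])) {
      vars <- selections[[trait]][[set_name]]
      for (kind in models) {
        ev <- fit_and_evaluate(X, y, vars, kind, train_fraction, cv_folds,
                               seed = sub_seed(seed, ti))
        evals[[trait]][[set_name]][[kind]] <- ev
        rows[[length(rows) + 1L]] <- data.frame(
          trait = trait, set = set_name, model = kind, r2 = ev$r2,
          r2_pearson = ev$r2_pearson, rrmse_pct = ev$rrmse_pct,
          n_vars = length(vars), n_test = ev$n)
      }
    }
  }
  list(grid = do.call(rbind, rows), evals = evals)
}
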
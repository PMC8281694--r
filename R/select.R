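# Variable selection: Boruta shadow features, permutation importance, genetic
# algorithm, LASSO, and recursive feature elimination, plus averaging of
# importances over repeated runs.

new_selection_result <- function(method, importances, decision, top_k, seed,
                                 extra = list()) {
  structure(c(list(method = method, importances = importances,
                   decision = decision, top_k = top_k, seed = seed), extra),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result [%s], %d candidates, top: %s\n", x$method,
              length(x$importances), paste(x$top_k, collapse = ", ")))
  invisible(x)
}

rank_top <- function(importances, k) {
  ord <- order(-importances, names(importances))   # lexicographic tie-break
  names(importances)[ord][seq_len(min(k, length(importances)))]
}

ranger_fit <- function(X, y, num_trees, seed, importance = "permutation",
                       mtry = NULL) {
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  ranger::ranger(x = as.data.frame(X), y = y, num.trees = num_trees,
                 mtry = min(mtry, ncol(X)), importance = importance,
                 num.threads = 1, seed = seed, verbose = FALSE)
}

#' Boruta all-relevant variable selection
#'
#' The shadow-feature scheme: each iteration appends a permuted copy of every
#' candidate column, fits a random forest with permutation importance, and
#' records a "hit" for every real variable whose importance exceeds the
#' maximal shadow importance. Variables are confirmed (rejected) when their
#' hit count is significantly above (below) the binomial(runs, 1/2) null by
#' a two-sided test at level `alpha` with Bonferroni correction; rejected
#' variables leave the active set. The importance score is the mean
#' importance over all iterations a variable participated in.
#'
#' @param X normalized feature matrix (rows >= 20).
#' @param y numeric response.
#' @param max_runs maximum iterations (default 20).
#' @param alpha test level (default 0.01, Bonferroni-corrected).
#' @param num_trees trees per forest (default 60).
#' @param k size of the returned top set (default 5).
#' @param seed integer seed; the procedure is deterministic given it.
#' @return a `selection_result` with decisions
#'   confirmed/rejected/tentative.
#' @export
boruta_select <- function(X, y, max_runs = 20, alpha = 0.01, num_trees = 60,
                          k = 5, seed = 1L) {
  p <- ncol(X)
  cn <- colnames(X)
  set.seed(seed)
  active <- rep(TRUE, p)
  hits <- integer(p); runs <- integer(p)
  imp_sum <- numeric(p)
  decision <- rep("tentative", p)
  for (it in seq_len(max_runs)) {
    act <- which(active)
    if (length(act) == 0) break
    Xa <- X[, act, drop = FALSE]
    Xs <- apply(Xa, 2, sample)
    colnames(Xs) <- paste0(".shadow", seq_along(act))
    fit <- ranger_fit(cbind(Xa, Xs), y, num_trees, seed = sub_seed(seed, it))
    imp <- fit$variable.importance
    imp_real <- imp[seq_along(act)]
    max_shadow <- max(imp[-seq_along(act)])
    hits[act] <- hits[act] + (imp_real > max_shadow)
    runs[act] <- runs[act] + 1L
    imp_sum[act] <- imp_sum[act] + imp_real
    # two-sided binomial decisions, Bonferroni over all candidates
    thr <- alpha / p
    p_conf <- stats::pbinom(hits[act] - 1L, runs[act], 0.5, lower.tail = FALSE)
    p_rej <- stats::pbinom(hits[act], runs[act], 0.5)
    decision[act][p_conf <= thr] <- "confirmed"
    newly_rej <- p_rej <= thr & decision[act] != "confirmed"
    decision[act][newly_rej] <- "rejected"
    active[act][decision[act] == "rejected"] <- FALSE
  }
  if (all(decision == "tentative"))
    warning("boruta: all variables tentative after max_runs")
  score <- ifelse(runs > 0, imp_sum / pmax(runs, 1L), 0)
  names(score) <- cn; names(decision) <- cn
  new_selection_result("boruta", score, decision, rank_top(score, k), seed,
                       list(hits = stats::setNames(hits, cn),
                            runs = stats::setNames(runs, cn), alpha = alpha))
}

#' Model-agnostic permutation variable importance
#'
#' Fits a base learner (random forest) and scores each variable by the mean
#' increase in RMSE loss when that column is permuted, averaged over
#' `n_permutations` independent permutations.
#'
#' @param X,y candidates and response.
#' @param n_permutations permutations per variable (default 2).
#' @param num_trees trees of the base forest (default 64).
#' @param k top-set size (default 5).
#' @param seed integer seed.
#' @return a `selection_result`; decision is `"n/a"` (ranking method).
#' @export
permimp_select <- function(X, y, n_permutations = 2, num_trees = 64, k = 5,
                           seed = 1L) {
  set.seed(seed)
  p <- ncol(X); n <- nrow(X)
  fit <- ranger_fit(X, y, num_trees, seed = seed, importance = "none")
  rmse <- function(pred) sqrt(mean((pred - y)^2))
  base <- rmse(stats::predict(fit, data = as.data.frame(X), num.threads = 1)$predictions)
  score <- numeric(p)
  chunk <- max(1L, floor(40000L / n))
  for (b in seq_len(n_permutations)) {
    for (s in seq(1L, p, by = chunk)) {
      e <- min(p, s + chunk - 1L)
      cols <- s:e
      big <- X[rep(seq_len(n), length(cols)), , drop = FALSE]
      for (ci in seq_along(cols)) {
        rows <- (ci - 1L) * n + seq_len(n)
        big[rows, cols[ci]] <- X[sample.int(n), cols[ci]]
      }
      pred <- stats::predict(fit, data = as.data.frame(big), num.threads = 1)$predictions
      for (ci in seq_along(cols)) {
        rows <- (ci - 1L) * n + seq_len(n)
        score[cols[ci]] <- score[cols[ci]] + (rmse(pred[rows]) - base)
      }
    }
  }
  score <- score / n_permutations
  names(score) <- colnames(X)
  new_selection_result("permimp", score,
                       stats::setNames(rep("n/a", p), colnames(X)),
                       rank_top(score, k), seed,
                       list(base_rmse = base, n_permutations = n_permutations))
}

# closed-form ridge fit (columns assumed centred/scaled by the caller's
# normalization); dual form when p > n
ridge_coef <- function(X, y, lambda) {
  n <- nrow(X); p <- ncol(X)
  ybar <- mean(y); yc <- y - ybar
  if (p <= n) {
    w <- solve(crossprod(X) + diag(lambda, p), crossprod(X, yc))
  } else {
    alpha <- solve(tcrossprod(X) + diag(lambda, n), yc)
    w <- crossprod(X, alpha)
  }
  list(w = w, intercept = ybar)
}

ridge_cv_rmse <- function(X, y, lambda, fold_id) {
  errs <- numeric(0)
  for (f in sort(unique(fold_id))) {
    te <- fold_id == f
    fit <- ridge_coef(X[!te, , drop = FALSE], y[!te], lambda)
    pred <- as.numeric(X[te, , drop = FALSE] %*% fit$w) + fit$intercept
    errs <- c(errs, (pred - y[te])^2)
  }
  sqrt(mean(errs))
}

#' Genetic-algorithm wrapper variable selection
#'
#' Binary chromosomes over the candidate columns; fitness is the negative
#' k-fold cross-validated RMSE of a ridge fit on the selected subset minus a
#' per-variable parsimony penalty. Tournament selection (size 2), uniform
#' crossover, bit-flip mutation, elitism of one. Importance is each column's
#' selection frequency across the final generation.
#'
#' @param X,y candidates and response.
#' @param population chromosomes per generation (>= 4; default 40).
#' @param generations generations (default 40).
#' @param crossover_p crossover probability (default 0.8).
#' @param mutation_p per-bit flip probability; default `1/ncol(X)` (one
#'   expected flip per child), which keeps mutation pressure independent of
#'   the candidate count.
#' @param init_p probability a bit starts on (default 0.05).
#' @param penalty fitness cost per selected variable (default 0.002 in
#'   response-RMSE units).
#' @param cv_folds folds inside the fitness (default 5).
#' @param ridge_lambda fixed small ridge penalty of the fitness learner.
#' @param k top-set size (default 5).
#' @param seed integer seed.
#' @return a `selection_result`; `extra$best_chromosome` is the fittest
#'   subset found.
#' @export
ga_select <- function(X, y, population = 40, generations = 40,
                      crossover_p = 0.8, mutation_p = NULL, init_p = 0.05,
                      penalty = 0.002, cv_folds = 5, ridge_lambda = 1,
                      k = 5, seed = 1L) {
  if (population < 4) stop("configuration error: population must be >= 4")
  set.seed(seed)
  p <- ncol(X); n <- nrow(X)
  if (is.null(mutation_p)) mutation_p <- 1 / p
  fold_id <- sample(rep(seq_len(cv_folds), length.out = n))
  fitness <- function(chrom) {
    sel <- which(chrom)
    if (length(sel) == 0) return(-Inf)
    -ridge_cv_rmse(X[, sel, drop = FALSE], y, ridge_lambda, fold_id) -
      penalty * length(sel)
  }
  pop <- matrix(stats::runif(population * p) < init_p, population, p)
  pop[rowSums(pop) == 0, 1] <- TRUE
  fit <- apply(pop, 1, fitness)
  for (g in seq_len(generations)) {
    newpop <- matrix(FALSE, population, p)
    best <- which.max(fit)
    newpop[1, ] <- pop[best, ]                       # elitism
    for (s in seq(2, population)) {
      i1 <- tournament(fit); i2 <- tournament(fit)
      child <- pop[i1, ]
      if (stats::runif(1) < crossover_p) {
        take2 <- stats::runif(p) < 0.5
        child[take2] <- pop[i2, take2]
      }
      flip <- stats::runif(p) < mutation_p
      child[flip] <- !child[flip]
      if (!any(child)) child[sample.int(p, 1)] <- TRUE
      newpop[s, ] <- child
    }
    pop <- newpop
    fit <- apply(pop, 1, fitness)
  }
  freq <- colMeans(pop)
  names(freq) <- colnames(X)
  best <- which.max(fit)
  new_selection_result("ga", freq,
                       stats::setNames(rep("n/a", p), colnames(X)),
                       rank_top(freq, k), seed,
                       list(best_chromosome = colnames(X)[pop[best, ]],
                            best_fitness = fit[best]))
}

tournament <- function(fit, size = 2) {
  cand <- sample.int(length(fit), size)
  cand[which.max(fit[cand])]
}

#' LASSO variable selection
#'
#' L1-penalized linear regression along a lambda path with the penalty chosen
#' by k-fold cross-validation (minimum mean CV error). Importance is the
#' absolute coefficient at the chosen penalty; exactly-zero coefficients are
#' rejected.
#'
#' @param X normalized candidates.
#' @param y response.
#' @param cv_folds folds (default 10).
#' @param lambda_grid optional lambda sequence (default: glmnet's path).
#' @param k top-set size (default 5).
#' @param seed integer seed (drives fold assignment).
#' @return a `selection_result`; `top_k` contains at most `k` nonzero-
#'   coefficient variables.
#' @export
lasso_select <- function(X, y, cv_folds = 10, lambda_grid = NULL, k = 5,
                         seed = 1L) {
  set.seed(seed)
  fold_id <- sample(rep(seq_len(cv_folds), length.out = nrow(X)))
  cv <- glmnet::cv.glmnet(X, y, alpha = 1, foldid = fold_id,
                          lambda = lambda_grid, standardize = FALSE)
  beta <- as.numeric(stats::coef(cv, s = "lambda.min"))[-1]
  score <- abs(beta)
  names(score) <- colnames(X)
  decision <- ifelse(score > 0, "confirmed", "rejected")
  nonzero <- names(score)[score > 0]
  if (length(nonzero) == 0) warning("lasso: all coefficients zero at lambda.min")
  top <- rank_top(score[score > 0], k)
  new_selection_result("lasso", score, decision, top, seed,
                       list(lambda_min = cv$lambda.min))
}

#' Recursive feature elimination
#'
#' Iteratively fits a random forest, drops the `step_frac` lowest-importance
#' share of the remaining variables (at least one), and records the
#' elimination order. The forest's out-of-bag RMSE at each subset size acts
#' as the cross-validation estimate that picks the best size. Importance is
#' the reverse elimination rank; `top_k` is the best-size subset ordered by
#' that rank and truncated to `k`, so it may hold fewer than `k` names when
#' the optimal subset is smaller.
#'
#' @param X,y candidates and response.
#' @param step_frac fraction of remaining variables dropped per iteration
#'   (default 0.1).
#' @param num_trees trees per forest (default 100).
#' @param k top-set size cap (default 5).
#' @param seed integer seed.
#' @return a `selection_result`; `extra$oob_rmse` maps subset size to OOB
#'   RMSE, `extra$best_size` is the chosen size.
#' @export
rfe_select <- function(X, y, step_frac = 0.1, num_trees = 100, k = 5,
                       seed = 1L) {
  set.seed(seed)
  p <- ncol(X); cn <- colnames(X)
  remaining <- cn
  elim_order <- character(0)                 # first eliminated first
  sizes <- integer(0); oob <- numeric(0); subsets <- list()
  it <- 0L
  while (length(remaining) >= 1) {
    it <- it + 1L
    fit <- ranger_fit(X[, remaining, drop = FALSE], y, num_trees,
                      seed = sub_seed(seed, it), importance = "impurity")
    sizes <- c(sizes, length(remaining))
    oob <- c(oob, sqrt(fit$prediction.error))
    subsets[[length(subsets) + 1L]] <- remaining
    if (length(remaining) == 1) { elim_order <- c(elim_order, remaining); break }
    imp <- fit$variable.importance
    drop_n <- max(1L, floor(step_frac * length(remaining)))
    ord <- order(imp, method = "radix")      # lowest importance first
    dropped <- remaining[ord[seq_len(drop_n)]]
    elim_order <- c(elim_order, dropped)
    remaining <- setdiff(remaining, dropped)
  }
  # importance: reverse elimination rank (last survivor highest)
  score <- stats::setNames(match(cn, elim_order), cn)
  names(score) <- cn
  best_i <- which.min(oob)
  best_subset <- subsets[[best_i]]
  decision <- stats::setNames(ifelse(cn %in% best_subset, "confirmed", "rejected"), cn)
  top <- rank_top(score[best_subset], k)
  new_selection_result("rfe", score, decision, top, seed,
                       list(oob_rmse = stats::setNames(oob, sizes),
                            best_size = sizes[best_i]))
}

#' Average importances over repeated selection runs
#'
#' Per-variable mean importance over repeats of one method, sorted
#' descending with a lexicographic column-name tie-break and truncated to
#' `k`.
#'
#' @param results list of `selection_result`s sharing method and candidates.
#' @param k top-set size (default 5).
#' @return a `selection_result` whose `importances` are the means; `top_k`
#'   respects any per-repeat cap (RFE may return < k names).
#' @export
average_and_rank <- function(results, k = 5) {
  if (length(results) == 0) stop("aggregation error: no results")
  meth <- unique(vapply(results, function(r) r$method, character(1)))
  if (length(meth) != 1) stop("aggregation error: mixed methods")
  cands <- lapply(results, function(r) names(r$importances))
  if (!all(vapply(cands, identical, logical(1), cands[[1]])))
    stop("aggregation error: inconsistent candidate sets")
  imp <- rowMeans(vapply(results, function(r) r$importances,
                         numeric(length(cands[[1]]))))
  names(imp) <- cands[[1]]
  # cap honours a per-repeat top-set shorter than k (RFE's CV-optimal size)
  cap <- min(k, max(vapply(results, function(r) length(r$top_k), integer(1))))
  new_selection_result(meth, imp,
                       stats::setNames(rep("n/a", length(imp)), names(imp)),
                       rank_top(imp, cap), results[[1]]$seed,
                       list(repeats = length(results)))
}

#' Run one selection method with repeats and averaged importances
#'
#' @param X,y candidates and response.
#' @param method one of `"boruta"`, `"permimp"`, `"ga"`, `"lasso"`, `"rfe"`.
#' @param repeats repeated runs with distinct derived seeds (default 10).
#' @param seed master seed.
#' @param k top-set size (default 5).
#' @param ... passed to the method.
#' @return the averaged `selection_result`.
#' @export
run_selection <- function(X, y, method = c("boruta", "permimp", "ga", "lasso", "rfe"),
                          repeats = 10, seed = 1L, k = 5, ...) {
  method <- match.arg(method)
  fn <- switch(method, boruta = boruta_select, permimp = permimp_select,
               ga = ga_select, lasso = lasso_select, rfe = rfe_select)
  res <- lapply(seq_len(repeats), function(r) fn(X, y, k = k, seed = sub_seed(seed, r), ...))
  average_and_rank(res, k = k)
}
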
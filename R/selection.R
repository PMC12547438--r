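#' Leave-one-out predictions and LOOMAE
#'
#' For each case j the model is refitted on the other N-1 cases (with a seed
#' derived from `params$seed` and j) and used to predict case j. The summary
#' is the leave-one-out mean absolute error,
#' `LOOMAE = mean(|y_j - yhat_j|)`; absolute rather than squared error so
#' isolated badly-predicted stations do not dominate.
#'
#' @param table station data frame.
#' @param predictors predictor columns to use.
#' @param params a [boost_params()].
#' @param response_name response column.
#' @param log_transform if `TRUE`, models are fitted to `log1p(response)` and
#'   predictions back-transformed with `expm1` before the error is taken.
#'   Off by default: the analysis operates on untransformed counts.
#' @return object of class `loo_result`: list with `per_case_prediction`,
#'   `abs_error` and `loomae` (particles/kg).
#' @examples
#' st <- generate_station_dataset(n = 12, seed = 1)$stations
#' loo <- loo_predictions(st, params = boost_params(ntrees = 10, seed = 1))
#' loo$loomae
#' @export
loo_predictions <- function(table, predictors = NULL, params = boost_params(),
                            response_name = "mp_count",
                            log_transform = FALSE) {
  if (is.null(predictors)) predictors <- guess_predictors(table)
  n <- nrow(table)
  if (n < 2) stop("leave-one-out needs at least 2 cases")
  y <- as.numeric(table[[response_name]])
  X <- as.matrix(table[, predictors, drop = FALSE])
  if (!all(is.finite(y)) || !all(is.finite(X)))
    stop("non-finite response or predictor values")
  yfit <- if (log_transform) log1p(y) else y
  pred <- if (params$depth == 1L) {
    # stump fast path: the whole LOO pass runs in compiled code
    tree_seeds <- matrix(vapply(seq_len(n), function(j)
      derive_seed_vec(derive_seed(params$seed, 201L, j), 101L,
                      seq_len(params$ntrees)),
      integer(params$ntrees)), nrow = params$ntrees, ncol = n)
    as.numeric(loo_boost_stump_cpp(X, yfit, params$minobs, params$shrinkage,
                                   params$bag_fraction, tree_seeds))
  } else {
    vapply(seq_len(n), function(j) {
      params_j <- params
      params_j$seed <- derive_seed(params$seed, 201L, j)
      fit <- boost_fit_raw(X[-j, , drop = FALSE], yfit[-j], params_j)
      boost_predict_cpp(fit$nodes, fit$offsets, fit$baseline,
                        params_j$shrinkage, X[j, , drop = FALSE])
    }, numeric(1))
  }
  if (log_transform) pred <- expm1(pred)
  abs_error <- abs(y - pred)
  structure(list(per_case_prediction = pred, abs_error = abs_error,
                 loomae = mean(abs_error)),
            class = "loo_result")
}

#' Replicated LOOMAE
#'
#' Boosting is stochastic (per-tree subsampling), so a single LOOMAE value
#' carries run-to-run noise; this runs the full leave-one-out pass `reps`
#' times with distinct derived seeds and returns the mean and standard
#' deviation of the rep-level LOOMAE values.
#'
#' @inheritParams loo_predictions
#' @param reps number of replicate LOO passes (>= 1). The survey analysis
#'   uses 100; tests and examples use fewer.
#' @return list with `mean`, `sd` (`NA` when `reps == 1`), and the rep-level
#'   `values`.
#' @export
replicated_loomae <- function(table, predictors = NULL,
                              params = boost_params(), reps = 100,
                              response_name = "mp_count",
                              log_transform = FALSE) {
  if (reps < 1) stop("reps must be >= 1")
  values <- vapply(seq_len(reps), function(r) {
    params_r <- params
    params_r$seed <- derive_seed(params$seed, 301L, r)
    loo_predictions(table, predictors, params_r, response_name,
                    log_transform)$loomae
  }, numeric(1))
  list(mean = mean(values),
       sd = if (reps > 1) sd(values) else NA_real_,
       values = values)
}

#' Permutation importance of each predictor
#'
#' For each of `reps` replicates, the full model (all candidate predictors)
#' is fitted with a fresh derived seed and its training-set MAE recorded;
#' then each predictor column in turn is randomly permuted (seeded) and the
#' MAE of the fitted model on the permuted table recomputed. A predictor's
#' importance contribution is the MAE increase under permutation, and the
#' table reports per-predictor means and standard deviations over replicates.
#' This is the training-set refit member of the permutation-importance
#' family, chosen for determinism; individual values can be slightly
#' negative by sampling noise, so only rankings should be interpreted.
#'
#' @inheritParams replicated_loomae
#' @return object of class `importance_table`: data frame with columns
#'   `predictor`, `mean_importance`, `sd`, `reps`, sorted by decreasing mean
#'   importance.
#' @export
permutation_importance <- function(table, predictors = NULL,
                                   params = boost_params(), reps = 100,
                                   response_name = "mp_count",
                                   log_transform = FALSE) {
  if (is.null(predictors)) predictors <- guess_predictors(table)
  missing_cols <- setdiff(predictors, names(table))
  if (length(missing_cols) > 0)
    stop("predictors not in table: ", paste(missing_cols, collapse = ", "))
  if (reps < 1) stop("reps must be >= 1")
  n <- nrow(table)
  y <- as.numeric(table[[response_name]])
  X <- as.matrix(table[, predictors, drop = FALSE])
  if (!all(is.finite(y)) || !all(is.finite(X)))
    stop("non-finite response or predictor values")
  yfit <- if (log_transform) log1p(y) else y

  imp <- matrix(NA_real_, nrow = reps, ncol = length(predictors),
                dimnames = list(NULL, predictors))
  for (r in seq_len(reps)) {
    params_r <- params
    params_r$seed <- derive_seed(params$seed, 401L, r)
    fit <- boost_fit_raw(X, yfit, params_r)
    base_pred <- as.numeric(fit$fitted)
    if (log_transform) base_pred <- expm1(base_pred)
    base_mae <- mean(abs(y - base_pred))
    for (i in seq_along(predictors)) {
      set.seed(derive_seed(params$seed, 402L, r, i))
      Xp <- X
      Xp[, i] <- Xp[sample.int(n), i]
      perm_pred <- boost_predict_cpp(fit$nodes, fit$offsets, fit$baseline,
                                     params_r$shrinkage, Xp)
      if (log_transform) perm_pred <- expm1(perm_pred)
      imp[r, i] <- mean(abs(y - perm_pred)) - base_mae
    }
  }
  out <- data.frame(predictor = predictors,
                    mean_importance = colMeans(imp),
                    sd = if (reps > 1) apply(imp, 2, sd) else NA_real_,
                    reps = reps, stringsAsFactors = FALSE)
  out <- out[order(-out$mean_importance, seq_len(nrow(out))), ]
  rownames(out) <- NULL
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Forward-selection curve of replicated LOOMAE against model size
#'
#' Orders the candidate predictors by decreasing mean permutation importance
#' (from the full model), then computes the replicated LOOMAE of the models
#' containing the first k variables for k = 1..p. The minimum of the curve
#' locates the best model size.
#'
#' @inheritParams replicated_loomae
#' @param importance optionally a precomputed [permutation_importance()]
#'   table; when `NULL` it is computed with the same `reps`.
#' @return object of class `selection_curve`: list with `variable_order`,
#'   `mean_loomae`, `sd_loomae` (each length p) and `reps`.
#' @export
selection_curve <- function(table, predictors = NULL,
                            params = boost_params(), reps = 100,
                            response_name = "mp_count",
                            log_transform = FALSE, importance = NULL) {
  if (is.null(predictors)) predictors <- guess_predictors(table)
  if (length(predictors) < 1) stop("need at least one predictor")
  if (is.null(importance))
    importance <- permutation_importance(table, predictors, params, reps,
                                         response_name, log_transform)
  variable_order <- importance$predictor
  p <- length(variable_order)
  mean_loomae <- numeric(p)
  sd_loomae <- numeric(p)
  for (k in seq_len(p)) {
    params_k <- params
    params_k$seed <- derive_seed(params$seed, 501L, k)
    rl <- replicated_loomae(table, variable_order[seq_len(k)], params_k,
                            reps, response_name, log_transform)
    mean_loomae[k] <- rl$mean
    sd_loomae[k] <- rl$sd
  }
  structure(list(variable_order = variable_order,
                 mean_loomae = mean_loomae, sd_loomae = sd_loomae,
                 reps = reps),
            class = "selection_curve")
}

#' @export
print.selection_curve <- function(x, ...) {
  cat("LOOMAE selection curve (", x$reps, "reps ):\n")
  print(data.frame(size = seq_along(x$variable_order),
                   variable_added = x$variable_order,
                   mean_loomae = x$mean_loomae, sd = x$sd_loomae))
  invisible(x)
}

#' Best predictor subset from a selection curve
#'
#' Returns the first k variables of the importance ordering, where k is the
#' position of the minimum mean LOOMAE; exact ties resolve toward the
#' smaller (more parsimonious) model.
#'
#' @param curve a [selection_curve()] result.
#' @return character vector of selected predictor names.
#' @export
select_best_model <- function(curve) {
  stopifnot(inherits(curve, "selection_curve"))
  if (length(curve$mean_loomae) < 1) stop("empty selection curve")
  k <- which.min(curve$mean_loomae)  # first minimum = smallest size on ties
  curve$variable_order[seq_len(k)]
}

#' Choose boosting parameters by replicated LOOMAE over a grid
#'
#' Evaluates every candidate parameter set on the full predictor list and
#' returns the one with the lowest mean LOOMAE (ties resolve to the earliest
#' grid entry).
#'
#' @inheritParams replicated_loomae
#' @param grid non-empty list of [boost_params()] candidates.
#' @return the winning `boost_params`, with attributes `loomae_mean` (vector
#'   over the grid) and `grid_index`.
#' @export
tune_parameters <- function(table, predictors = NULL, grid, reps = 100,
                            response_name = "mp_count",
                            log_transform = FALSE) {
  if (!is.list(grid) || length(grid) < 1) stop("grid must be a non-empty list")
  ok <- vapply(grid, inherits, logical(1), what = "boost_params")
  if (!all(ok)) stop("every grid entry must be a boost_params object")
  means <- vapply(seq_along(grid), function(g) {
    params_g <- grid[[g]]
    params_g$seed <- derive_seed(grid[[g]]$seed, 601L, g)
    replicated_loomae(table, predictors, params_g, reps, response_name,
                      log_transform)$mean
  }, numeric(1))
  best <- which.min(means)
  out <- grid[[best]]
  attr(out, "loomae_mean") <- means
  attr(out, "grid_index") <- best
  out
}
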
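#' Boosting hyperparameters
#'
#' Container for the gradient-boosting configuration. The survey analysis
#' this package implements uses `ntrees = 400`, `depth = 1` (regression
#' stumps) and `minobs = 10`; those are the defaults here. Shrinkage and the
#' bag fraction follow the conventional defaults of stochastic gradient
#' boosting (0.1 and 0.5) and are exposed for tuning.
#'
#' @param ntrees number of boosting iterations (>= 0).
#' @param depth number of sequential split levels per tree (1 = stump).
#' @param minobs minimum observations in any terminal node (>= 1).
#' @param shrinkage learning rate in (0, 1].
#' @param bag_fraction fraction of rows subsampled (without replacement) for
#'   each tree, in (0, 1].
#' @param seed integer seed; per-tree subsampling seeds are derived from it.
#' @return an object of class `boost_params`.
#' @examples
#' boost_params()
#' boost_params(ntrees = 100, shrinkage = 0.05)
#' @export
boost_params <- function(ntrees = 400L, depth = 1L, minobs = 10L,
                         shrinkage = 0.1, bag_fraction = 0.5, seed = 1L) {
  ntrees <- as.integer(ntrees); depth <- as.integer(depth)
  minobs <- as.integer(minobs); seed <- as.integer(seed)
  if (is.na(ntrees) || ntrees < 0) stop("ntrees must be >= 0")
  if (is.na(depth) || depth < 1) stop("depth must be >= 1")
  if (is.na(minobs) || minobs < 1) stop("minobs must be >= 1")
  if (!is.numeric(shrinkage) || shrinkage <= 0 || shrinkage > 1)
    stop("shrinkage must be in (0, 1]")
  if (!is.numeric(bag_fraction) || bag_fraction <= 0 || bag_fraction > 1)
    stop("bag_fraction must be in (0, 1]")
  structure(list(ntrees = ntrees, depth = depth, minobs = minobs,
                 shrinkage = shrinkage, bag_fraction = bag_fraction,
                 seed = seed),
            class = "boost_params")
}

#' @export
print.boost_params <- function(x, ...) {
  cat("Boosting parameters: ntrees =", x$ntrees, ", depth =", x$depth,
      ", minobs =", x$minobs, ", shrinkage =", x$shrinkage,
      ", bag_fraction =", x$bag_fraction, ", seed =", x$seed, "\n")
  invisible(x)
}

#' Fit a single regression tree by greedy squared-error reduction
#'
#' Base learner of the boosting ensemble, exposed for inspection and testing.
#' At each level the best split over all (feature, midpoint-between-distinct-
#' values) candidates is taken, subject to both sides holding at least
#' `minobs` rows; leaf values are in-leaf target means. If no candidate
#' reduces the SSE the node stays a single leaf. Ties in SSE reduction break
#' toward the lowest feature index, then the lowest threshold.
#'
#' @param features numeric matrix (rows = cases) with column names.
#' @param targets numeric response vector, `length(targets) == nrow(features)`.
#' @param depth number of split levels (1 = stump).
#' @param minobs minimum rows per terminal node.
#' @return an object of class `regression_tree`: the node matrix plus the
#'   feature names used to decode split indices.
#' @examples
#' x <- matrix(c(1, 2, 3, 10, 11, 12), ncol = 1, dimnames = list(NULL, "x"))
#' fit_tree(x, c(0, 0, 0, 5, 5, 5), depth = 1, minobs = 1)
#' @export
fit_tree <- function(features, targets, depth = 1L, minobs = 10L) {
  features <- as.matrix(features)
  if (nrow(features) < 1 || length(targets) != nrow(features))
    stop("features and targets must have matching, positive length")
  if (!all(is.finite(features)) || !all(is.finite(targets)))
    stop("features and targets must be finite")
  nodes <- fit_tree_cpp(features, as.numeric(targets),
                        as.integer(depth), as.integer(minobs))
  colnames(nodes) <- c("feature", "threshold", "left", "right", "value")
  structure(list(nodes = nodes, feature_names = colnames(features)),
            class = "regression_tree")
}

#' @export
predict.regression_tree <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  as.numeric(tree_predict_cpp(object$nodes, X))
}

#' Fit a stochastic gradient-boosted stump/tree ensemble
#'
#' Squared-error boosting on the untransformed response: the model starts at
#' the training-response mean, and each of `ntrees` iterations fits a depth-
#' `depth` regression tree to the current residuals of a freshly subsampled
#' `bag_fraction` of the rows (without replacement; the subsample for tree
#' *m* is drawn from a generator seeded by `(seed, m)`), then shifts every
#' fitted value by `shrinkage` times that tree.
#'
#' @param table data frame holding the response and predictor columns
#'   (a station table from [generate_station_dataset()] or
#'   [read_station_csv()]).
#' @param response_name name of the response column (particles per kg
#'   dry-weight sediment).
#' @param predictor_names character vector of predictor columns to use.
#' @param params a [boost_params()] object.
#' @return an object of class `boosted_model` with elements `baseline`
#'   (training-response mean), `trees`, `shrinkage`, `feature_names`,
#'   `fitted` (training fitted values) and `params`.
#' @examples
#' st <- generate_station_dataset(n = 40, seed = 1)$stations
#' m <- fit_boosted_model(st, params = boost_params(ntrees = 25, seed = 1))
#' head(predict(m, st))
#' @export
fit_boosted_model <- function(table, response_name = "mp_count",
                              predictor_names = NULL,
                              params = boost_params()) {
  stopifnot(inherits(params, "boost_params"))
  if (is.null(predictor_names)) predictor_names <- guess_predictors(table)
  missing_cols <- setdiff(c(response_name, predictor_names), names(table))
  if (length(missing_cols) > 0)
    stop("columns not found in table: ", paste(missing_cols, collapse = ", "))
  y <- as.numeric(table[[response_name]])
  X <- as.matrix(table[, predictor_names, drop = FALSE])
  if (!all(is.finite(y)) || !all(is.finite(X)))
    stop("non-finite response or predictor values")
  fit <- boost_fit_raw(X, y, params)
  colnames(fit$nodes) <- c("feature", "threshold", "left", "right", "value")
  structure(list(baseline = fit$baseline, nodes = fit$nodes,
                 tree_offsets = as.integer(fit$offsets),
                 shrinkage = params$shrinkage,
                 feature_names = predictor_names,
                 fitted = as.numeric(fit$fitted), params = params),
            class = "boosted_model")
}

# vectorized equivalent of derive_seed(seed, salt, i) over a whole index
# vector (all products stay below 2^53, so doubles are exact)
derive_seed_vec <- function(seed, salt, idx) {
  m <- 2147483647
  h <- as.double(seed) %% m
  h <- (h * 48271 + as.double(salt) + 1) %% m
  h <- (h * 48271 + as.double(idx) + 1) %% m
  as.integer(h %% (m - 1) + 1)
}

# matrix-level fit: the hot path shared by fit_boosted_model, the LOO loop
# and permutation importance
boost_fit_raw <- function(X, y, params) {
  n <- nrow(X)
  n_bag <- max(1L, as.integer(ceiling(params$bag_fraction * n)))
  tree_seeds <- if (params$ntrees > 0)
    derive_seed_vec(params$seed, 101L, seq_len(params$ntrees))
  else integer(0)
  boost_fit_cpp(X, y, n_bag, params$depth, params$minobs,
                params$shrinkage, tree_seeds)
}

#' Extract the tree list of a boosted model
#'
#' The ensemble is stored internally as one flat node matrix; this splits it
#' back into per-tree node matrices (child indices local to each tree).
#'
#' @param model a `boosted_model`.
#' @return list of node matrices, one per boosting iteration.
#' @export
model_trees <- function(model) {
  stopifnot(inherits(model, "boosted_model"))
  off <- model$tree_offsets
  lapply(seq_len(length(off) - 1), function(m) {
    rows <- (off[m] + 1):off[m + 1]
    tm <- model$nodes[rows, , drop = FALSE]
    kids <- tm[, c("left", "right")]
    kids[kids >= 0] <- kids[kids >= 0] - off[m]
    tm[, c("left", "right")] <- kids
    tm
  })
}

# station-table convention: every column that is not an identifier,
# coordinate or the response is a predictor
guess_predictors <- function(table) {
  setdiff(names(table), c("station_id", "cell_id", "lon", "lat", "mp_count"))
}

#' Predict from a boosted model
#'
#' Evaluates `baseline + shrinkage * sum(tree outputs)` row-wise; fully
#' deterministic.
#'
#' @param object a `boosted_model`.
#' @param newdata data frame (or matrix) supplying every model feature.
#' @param ... unused.
#' @return numeric vector of predictions, one per row of `newdata`.
#' @export
predict.boosted_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  missing_cols <- setdiff(object$feature_names, names(newdata))
  if (length(missing_cols) > 0)
    stop("missing feature columns: ", paste(missing_cols, collapse = ", "))
  X <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  as.numeric(boost_predict_cpp(object$nodes, object$tree_offsets,
                               object$baseline, object$shrinkage, X))
}

#' @export
print.boosted_model <- function(x, ...) {
  cat("Boosted regression-tree model:", length(x$tree_offsets) - 1,
      "trees, depth", x$params$depth,
      "\n  baseline =", format(x$baseline),
      "\n  features:", paste(x$feature_names, collapse = ", "), "\n")
  invisible(x)
}

#' Partial-dependence curve of one predictor
#'
#' The marginal effect of one explanatory variable with all the others held
#' at their observed values: for each grid value `v` the model is evaluated
#' on the whole table with the chosen feature forced to `v`, and the
#' predictions averaged.
#'
#' @param model a `boosted_model`.
#' @param table data frame of background rows (typically the training data).
#' @param feature name of the feature to profile.
#' @param grid numeric vector of values at which to evaluate the curve;
#'   defaults to an even grid over the observed feature range.
#' @return data frame with columns `grid` and `partial` (mean prediction).
#' @examples
#' st <- generate_station_dataset(n = 40, seed = 1)$stations
#' m <- fit_boosted_model(st, params = boost_params(ntrees = 25, seed = 1))
#' pd <- partial_dependence(m, st, "salinity_range")
#' @export
partial_dependence <- function(model, table, feature, grid = NULL) {
  stopifnot(inherits(model, "boosted_model"))
  if (!feature %in% model$feature_names)
    stop("unknown feature: ", feature)
  if (is.null(grid))
    grid <- seq(min(table[[feature]]), max(table[[feature]]), length.out = 50)
  if (length(grid) < 1) stop("grid must be non-empty")
  partial <- vapply(grid, function(v) {
    tbl <- table
    tbl[[feature]] <- v
    mean(predict(model, tbl))
  }, numeric(1))
  data.frame(grid = as.numeric(grid), partial = partial)
}

#' Serialize a boosted model to JSON
#'
#' Writes baseline, shrinkage, feature names, boosting parameters and the
#' full tree list (node matrices) to a JSON file at full precision, so the
#' model can be reloaded for later projection onto a grid.
#'
#' @param model a `boosted_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "boosted_model"))
  obj <- list(
    format = "seabedmp_boosted_model",
    baseline = model$baseline,
    shrinkage = model$shrinkage,
    feature_names = model$feature_names,
    params = unclass(model$params),
    trees = lapply(model_trees(model), function(tm) {
      m <- unname(as.matrix(tm))
      # row-major list of nodes, each [feature, threshold, left, right, value]
      lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
    })
  )
  # I(17) significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a boosted model from JSON
#'
#' @param path path to a file written by [write_model_json()].
#' @return a `boosted_model`.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "seabedmp_boosted_model"))
    stop("not a seabedmp model file: ", path)
  trees <- lapply(obj$trees, function(tr) {
    do.call(rbind, lapply(tr, function(node) {
      vapply(node, function(v) if (is.null(v)) NA_real_ else as.numeric(v),
             numeric(1))
    }))
  })
  # re-flatten with global child indices
  sizes <- vapply(trees, nrow, integer(1))
  offsets <- c(0L, cumsum(sizes))
  nodes <- do.call(rbind, lapply(seq_along(trees), function(m) {
    tm <- trees[[m]]
    kids <- tm[, 3:4]
    kids[kids >= 0] <- kids[kids >= 0] + offsets[m]
    tm[, 3:4] <- kids
    tm
  }))
  if (is.null(nodes)) nodes <- matrix(numeric(0), ncol = 5)
  colnames(nodes) <- c("feature", "threshold", "left", "right", "value")
  p <- obj$params
  params <- boost_params(p$ntrees, p$depth, p$minobs, p$shrinkage,
                         p$bag_fraction, p$seed)
  structure(list(baseline = as.numeric(obj$baseline), nodes = nodes,
                 tree_offsets = as.integer(offsets),
                 shrinkage = as.numeric(obj$shrinkage),
                 feature_names = as.character(unlist(obj$feature_names)),
                 fitted = NULL, params = params),
            class = "boosted_model")
}
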
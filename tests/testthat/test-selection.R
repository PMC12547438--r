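make_tiny_table <- function(y, seed = 1) {
  set.seed(seed)
  data.frame(x1 = rnorm(length(y)), x2 = rnorm(length(y)), mp_count = y)
}

test_that("LOO predictions reduce to leave-one-out means when ntrees = 0", {
  tbl <- make_tiny_table(rep(4.2, 8))
  loo <- loo_predictions(tbl, c("x1", "x2"), boost_params(ntrees = 0))
  expect_equal(loo$per_case_prediction, rep(4.2, 8))
  expect_equal(loo$loomae, 0)

  tbl2 <- make_tiny_table(c(0, 3))
  loo2 <- loo_predictions(tbl2, c("x1", "x2"), boost_params(ntrees = 0))
  expect_equal(loo2$per_case_prediction, c(3, 0))
  expect_equal(loo2$loomae, 3)
  expect_error(loo_predictions(tbl2[1, ], c("x1", "x2")), "at least 2")
})

test_that("loomae equals the one-line recomputation from the returned vectors", {
  st <- generate_station_dataset(n = 20, seed = 31)$stations
  loo <- loo_predictions(st, params = boost_params(ntrees = 30, seed = 2))
  expect_equal(loo$loomae,
               mean(abs(st$mp_count - loo$per_case_prediction)),
               tolerance = 1e-15)
  expect_equal(loo$abs_error, abs(st$mp_count - loo$per_case_prediction))
})

test_that("stump LOO fast path agrees with the generic per-fit path", {
  st <- generate_station_dataset(n = 25, seed = 17)$stations
  p <- boost_params(ntrees = 50, seed = 9)
  loo <- loo_predictions(st, params = p)
  X <- as.matrix(st[, default_predictors()])
  y <- st$mp_count
  pred_generic <- vapply(seq_len(25), function(j) {
    pj <- p
    pj$seed <- derive_seed(p$seed, 201L, j)
    fit <- seabedmp:::boost_fit_raw(X[-j, , drop = FALSE], y[-j], pj)
    seabedmp:::boost_predict_cpp(fit$nodes, fit$offsets, fit$baseline,
                                 p$shrinkage, X[j, , drop = FALSE])
  }, numeric(1))
  expect_equal(loo$per_case_prediction, pred_generic, tolerance = 1e-10)
})

test_that("replicated LOOMAE has zero spread for deterministic fits", {
  st <- generate_station_dataset(n = 15, seed = 3)$stations
  p <- boost_params(ntrees = 20, bag_fraction = 1, seed = 7)
  rl <- replicated_loomae(st, params = p, reps = 4)
  expect_equal(rl$sd, 0)
  expect_equal(rl$values, rep(rl$mean, 4))

  rl1 <- replicated_loomae(st, params = boost_params(ntrees = 20, seed = 7),
                           reps = 1)
  expect_true(is.na(rl1$sd))
  expect_equal(rl1$mean, rl1$values[1])
  expect_error(replicated_loomae(st, reps = 0), "reps")
})

test_that("replicate means from independent streams agree within Monte-Carlo error", {
  st <- generate_station_dataset(n = 20, seed = 23)$stations
  p1 <- boost_params(ntrees = 30, seed = 100)
  p2 <- boost_params(ntrees = 30, seed = 200)
  r1 <- replicated_loomae(st, params = p1, reps = 30)
  r2 <- replicated_loomae(st, params = p2, reps = 30)
  expect_lt(abs(r1$mean - r2$mean),
            3 * sqrt(r1$sd^2 / 30 + r2$sd^2 / 30) + 1e-9)
})

test_that("permutation importance is exactly zero for a constant column", {
  st <- generate_station_dataset(n = 25, seed = 41)$stations
  st$flat <- 1.0
  preds <- c(default_predictors(), "flat")
  imp <- permutation_importance(st, preds,
                                boost_params(ntrees = 30, seed = 5),
                                reps = 3)
  expect_equal(imp$mean_importance[imp$predictor == "flat"], 0)
})

test_that("a strong noiseless single-predictor signal tops the importance ranking", {
  for (s in 1:5) {
    df <- step_table(n = 40, a = 500, b = 400, thr = 0, seed = 70 + s,
                     p_extra = 4)
    imp <- permutation_importance(df, c("x1", paste0("z", 1:4)),
                                  boost_params(ntrees = 100, seed = s),
                                  reps = 5)
    expect_equal(imp$predictor[1], "x1")
  }
})

test_that("single-predictor curves reduce to replicated LOOMAE", {
  st <- generate_station_dataset(n = 15, seed = 51)$stations
  p <- boost_params(ntrees = 15, seed = 3)
  cv <- selection_curve(st, "depth", p, reps = 3)
  expect_length(cv$mean_loomae, 1)
  p1 <- p
  p1$seed <- derive_seed(p$seed, 501L, 1)
  expect_equal(cv$mean_loomae,
               replicated_loomae(st, "depth", p1, reps = 3)$mean)
  expect_true(all(cv$mean_loomae >= 0))
})

test_that("best-model choice follows the argmin with parsimony on ties", {
  fake <- structure(list(variable_order = c("a", "b", "c", "d"),
                         mean_loomae = c(5, 3, 3, 4),
                         sd_loomae = rep(0, 4), reps = 1),
                    class = "selection_curve")
  expect_equal(select_best_model(fake), c("a", "b"))
  fake$mean_loomae <- c(5, 4, 3, 2)  # strictly decreasing -> all variables
  expect_equal(select_best_model(fake), c("a", "b", "c", "d"))
})

test_that("parameter tuning returns a grid member and prefers richer ensembles", {
  df <- step_table(n = 40, a = 800, b = 600, thr = 0, seed = 12, p_extra = 2)
  grid <- list(boost_params(ntrees = 1, minobs = 5, seed = 1),
               boost_params(ntrees = 100, minobs = 5, seed = 1))
  best <- tune_parameters(df, c("x1", "z1", "z2"), grid, reps = 3)
  expect_equal(best$ntrees, 100)
  expect_true(attr(best, "grid_index") %in% seq_along(grid))
  single <- tune_parameters(df, c("x1", "z1", "z2"),
                            list(boost_params(ntrees = 5)), reps = 2)
  expect_equal(single$ntrees, 5)
  expect_error(tune_parameters(df, c("x1"), list(), reps = 2), "non-empty")
})

test_that("the log-transform switch is off by default and changes the fit", {
  expect_false(formals(loo_predictions)$log_transform)
  expect_false(formals(selection_curve)$log_transform)
  st <- generate_station_dataset(n = 15, seed = 61)$stations
  p <- boost_params(ntrees = 10, seed = 2)
  plain <- loo_predictions(st, params = p)
  logged <- loo_predictions(st, params = p, log_transform = TRUE)
  expect_false(isTRUE(all.equal(plain$loomae, logged$loomae)))
})
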
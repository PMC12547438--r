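test_that("constant targets yield a single leaf and no candidate split helps", {
  inst <- random_instance(12, 3, seed = 4)
  y <- rep(7.5, 12)
  tree <- fit_tree(inst$X, y, depth = 1, minobs = 1)
  expect_equal(nrow(tree$nodes), 1)
  expect_equal(unname(tree$nodes[1, "value"]), 7.5)
  oracle <- brute_force_stump(inst$X, y, minobs = 1)
  expect_equal(oracle$gain, 0)
})

test_that("stump split matches exhaustive enumeration on a 1-feature toy set", {
  X <- matrix(c(0.2, 0.9, 1.7, 3.1, 3.8, 4.4), ncol = 1,
              dimnames = list(NULL, "x"))
  y <- c(1, 2, 1.5, 10, 11, 10.5)
  tree <- fit_tree(X, y, depth = 1, minobs = 1)
  oracle <- brute_force_stump(X, y, minobs = 1)
  expect_equal(unname(tree$nodes[1, "feature"]), oracle$feature - 1)
  expect_equal(unname(tree$nodes[1, "threshold"]), oracle$threshold)
  left <- tree$nodes[tree$nodes[1, "left"] + 1, "value"]
  right <- tree$nodes[tree$nodes[1, "right"] + 1, "value"]
  expect_equal(unname(c(left, right)),
               c(oracle$left_value, oracle$right_value))
})

test_that("infeasible minobs returns the single-leaf mean", {
  inst <- random_instance(8, 2, seed = 9)
  tree <- fit_tree(inst$X, inst$y, depth = 1, minobs = 50)
  expect_equal(nrow(tree$nodes), 1)
  expect_equal(unname(tree$nodes[1, "value"]), mean(inst$y))
  expect_equal(predict(tree, as.data.frame(inst$X)),
               rep(mean(inst$y), 8))
})

test_that("deeper trees respect depth and minobs on every terminal node", {
  inst <- random_instance(60, 3, seed = 2)
  tree <- fit_tree(inst$X, inst$y, depth = 3, minobs = 5)
  nodes <- tree$nodes
  leaves <- which(nodes[, "feature"] < 0)
  # walk every training row to its leaf; count rows per leaf
  assign <- vapply(seq_len(60), function(i) {
    k <- 1
    d <- 0
    while (nodes[k, "feature"] >= 0) {
      f <- nodes[k, "feature"] + 1
      k <- if (inst$X[i, f] <= nodes[k, "threshold"]) nodes[k, "left"] + 1
           else nodes[k, "right"] + 1
      d <- d + 1
    }
    expect_lte(d, 3)
    k
  }, numeric(1))
  counts <- table(assign)
  expect_true(all(counts >= 5))
  expect_setequal(as.integer(names(counts)), leaves)  # every leaf reachable
})

test_that("empty ensemble predicts the response mean everywhere", {
  st <- generate_station_dataset(n = 20, seed = 5)$stations
  m <- fit_boosted_model(st, params = boost_params(ntrees = 0, seed = 1))
  expect_equal(predict(m, st), rep(mean(st$mp_count), 20))
})

test_that("a noiseless single-step response is fitted exactly by one stump", {
  df <- step_table(n = 24, a = 100, b = 50, thr = 0, seed = 3)
  p <- boost_params(ntrees = 1, depth = 1, minobs = 1, shrinkage = 1,
                    bag_fraction = 1, seed = 1)
  m <- fit_boosted_model(df, "mp_count", c("x1", "z1", "z2"), p)
  expect_equal(m$fitted, df$mp_count, tolerance = 1e-12)
  expect_equal(predict(m, df), df$mp_count, tolerance = 1e-12)
})

test_that("training SSE is non-increasing in tree count with full bags", {
  st <- generate_station_dataset(n = 40, seed = 11)$stations
  p <- boost_params(ntrees = 60, bag_fraction = 1, seed = 2)
  m <- fit_boosted_model(st, params = p)
  trees <- model_trees(m)
  fitted <- rep(m$baseline, 40)
  X <- as.matrix(st[, m$feature_names])
  sse <- numeric(length(trees) + 1)
  sse[1] <- sum((st$mp_count - fitted)^2)
  for (k in seq_along(trees)) {
    fitted <- fitted + m$shrinkage * eval_tree_r(trees[[k]], X)
    sse[k + 1] <- sum((st$mp_count - fitted)^2)
  }
  expect_true(all(diff(sse) <= 1e-8))
  expect_equal(fitted, m$fitted, tolerance = 1e-10)
})

test_that("prediction rule is baseline + shrinkage * tree sum (hand case)", {
  # single stump: x > 2 -> +1, else -1; baseline 10, shrinkage 0.5
  nodes <- matrix(c(0, 2, 1, 2, 0,
                    -1, NA, -1, -1, -1,
                    -1, NA, -1, -1, 1),
                  nrow = 3, byrow = TRUE,
                  dimnames = list(NULL, c("feature", "threshold", "left",
                                          "right", "value")))
  m <- structure(list(baseline = 10, nodes = nodes, tree_offsets = c(0L, 3L),
                      shrinkage = 0.5, feature_names = "x", fitted = NULL,
                      params = boost_params(ntrees = 1)),
                 class = "boosted_model")
  expect_equal(predict(m, data.frame(x = 3)), 10.5)
  expect_equal(predict(m, data.frame(x = c(1, 2, 2.1))), c(9.5, 9.5, 10.5))
})

test_that("fits are deterministic and predicting training rows returns fitted", {
  st <- generate_station_dataset(n = 30, seed = 13)$stations
  p <- boost_params(ntrees = 80, seed = 21)
  m1 <- fit_boosted_model(st, params = p)
  m2 <- fit_boosted_model(st, params = p)
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$fitted, m2$fitted)
  expect_equal(predict(m1, st), m1$fitted, tolerance = 1e-12)
})

test_that("missing feature columns and non-finite inputs are rejected", {
  st <- generate_station_dataset(n = 20, seed = 5)$stations
  m <- fit_boosted_model(st, params = boost_params(ntrees = 5, seed = 1))
  expect_error(predict(m, st[, 1:4]), "missing feature")
  st_bad <- st
  st_bad$mp_count[3] <- NA
  expect_error(fit_boosted_model(st_bad, params = boost_params(ntrees = 5)),
               "non-finite")
})

test_that("partial dependence is flat for ignored features and steps at stumps", {
  df <- step_table(n = 30, a = 20, b = 8, thr = 0.4, seed = 6)
  p <- boost_params(ntrees = 1, depth = 1, minobs = 1, shrinkage = 1,
                    bag_fraction = 1, seed = 1)
  m <- fit_boosted_model(df, "mp_count", c("x1", "z1", "z2"), p)
  # the single stump splits on x1, so z1 is ignored
  pd_z <- partial_dependence(m, df, "z1", grid = seq(-2, 2, length.out = 11))
  expect_lt(diff(range(pd_z$partial)), 1e-10)
  # the x1 curve is a two-level step located at the stump threshold
  thr <- m$nodes[1, "threshold"]
  pd_x <- partial_dependence(m, df, "x1",
                             grid = c(thr - 0.01, thr + 0.01))
  expect_equal(unname(diff(pd_x$partial)), 8, tolerance = 1e-10)
  # any curve value lies within the attainable prediction range
  preds <- predict(m, df)
  pd_all <- partial_dependence(m, df, "x1")
  expect_true(all(pd_all$partial >= min(preds) - 1e-9 &
                  pd_all$partial <= max(preds) + 1e-9))
  expect_error(partial_dependence(m, df, "nope"), "unknown feature")
})

test_that("model JSON round trip preserves predictions exactly", {
  st <- generate_station_dataset(n = 25, seed = 8)$stations
  m <- fit_boosted_model(st, params = boost_params(ntrees = 40, seed = 4))
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path)
  m2 <- read_model_json(path)
  expect_identical(predict(m2, st), predict(m, st))
  expect_identical(m2$feature_names, m$feature_names)
})

test_that("stump fits agree with an exhaustive oracle across random instances", {
  for (s in 1:25) {
    n <- sample(5:30, 1)
    p <- sample(1:5, 1)
    minobs <- sample(1:3, 1)
    inst <- random_instance(n, p, seed = 1000 + s)
    tree <- fit_tree(inst$X, inst$y, depth = 1, minobs = minobs)
    oracle <- brute_force_stump(inst$X, inst$y, minobs = minobs)
    if (is.na(oracle$feature)) {
      expect_equal(nrow(tree$nodes), 1)
    } else {
      expect_equal(unname(tree$nodes[1, "feature"]), oracle$feature - 1)
      expect_equal(unname(tree$nodes[1, "threshold"]), oracle$threshold,
                   tolerance = 1e-12)
    }
  }
})
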
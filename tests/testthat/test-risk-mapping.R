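test_that("abundance classification matches the published band edges", {
  expect_equal(as.character(classify_abundance(c(0, 1000, 1001, 2700, 3000.5))),
               c("low", "low", "moderately_elevated", "elevated",
                 "highly_elevated"))
  expect_equal(as.character(classify_abundance(c(2000, 2000.5, 3000))),
               c("moderately_elevated", "elevated", "elevated"))
  expect_error(classify_abundance(-1), ">= 0")
  expect_error(classify_abundance(NaN), "finite")
})

test_that("classification is monotone in abundance", {
  set.seed(5)
  v <- sort(runif(200, 0, 5000))
  bins <- classify_abundance(v)
  expect_true(all(diff(as.integer(bins)) >= 0))
})

test_that("surfaces equal row-wise model predictions and respect row order", {
  st <- generate_station_dataset(n = 30, seed = 2)$stations
  g <- generate_prediction_grid(nx = 6, ny = 5, seed = 3)
  m <- fit_boosted_model(st, params = boost_params(ntrees = 25, seed = 1))
  surf <- predict_surface(m, g)
  expect_equal(surf$value, predict(m, g))
  perm <- sample(nrow(g))
  surf2 <- predict_surface(m, g[perm, ])
  expect_equal(surf2$value[match(surf$cell_id, surf2$cell_id)], surf$value)

  m0 <- fit_boosted_model(st, params = boost_params(ntrees = 0))
  expect_equal(unique(predict_surface(m0, g)$value), m0$baseline)
  expect_error(predict_surface(m, g[, 1:3]), "missing feature")
})

test_that("a single stump paints exactly two values on a straddling grid", {
  df <- step_table(n = 20, a = 10, b = 4, thr = 0, seed = 4)
  p <- boost_params(ntrees = 1, depth = 1, minobs = 1, shrinkage = 1,
                    bag_fraction = 1, seed = 1)
  m <- fit_boosted_model(df, "mp_count", c("x1", "z1", "z2"), p)
  g <- data.frame(cell_id = sprintf("C%02d", 1:9),
                  lon = seq(-1, 1, length.out = 9), lat = rep(50, 9),
                  x1 = seq(-2, 2, length.out = 9), z1 = 0, z2 = 0)
  surf <- predict_surface(m, g)
  expect_equal(length(unique(surf$value)), 2)
})

test_that("polygon means follow cell-centre containment with boundaries inside", {
  surf <- toy_surface(c(1000, 3000, 500, 700), nx = 2)
  # the whole unit square: every cell
  all_ring <- square_ring(0, 0, 1, 1)
  ly_all <- risk_layer("all", "receptor", list(all_ring))
  expect_equal(polygon_mean_exposure(surf, ly_all)$mean_value,
               mean(surf$value))
  # left column only: cells at lon 0.25 valued 1000 and 500
  ly_left <- risk_layer("left", "receptor", list(square_ring(0, 0, 0.5, 1)))
  expect_equal(polygon_mean_exposure(surf, ly_left)$mean_value, 750)
  # top-row pair {1000, 3000} -> 2000 (first two cells are lat 0.25)
  ly_bottom <- risk_layer("bottom", "receptor",
                          list(square_ring(0, 0, 1, 0.5)))
  expect_equal(polygon_mean_exposure(surf, ly_bottom)$mean_value, 2000)
  # disjoint polygon -> no data
  ly_out <- risk_layer("out", "receptor", list(square_ring(5, 5, 6, 6)))
  res <- polygon_mean_exposure(surf, ly_out)
  expect_true(is.na(res$mean_value))
  expect_equal(res$n_cells, 0)
  # a cell centre exactly on the boundary counts as inside
  ly_edge <- risk_layer("edge", "receptor",
                        list(square_ring(0.25, 0.25, 2, 2)))
  expect_equal(polygon_mean_exposure(surf, ly_edge)$n_cells, 4)
})

test_that("ray-casting containment agrees with an independent implementation", {
  skip_if_not_installed("mgcv")
  set.seed(11)
  for (rep in 1:10) {
    layers <- generate_risk_layers(c(poly = "receptor"), 1,
                                   bbox = c(0, 10, 0, 10), seed = rep)
    ring <- layers[[1]]$polygons[[1]]
    px <- runif(200, 0, 10); py <- runif(200, 0, 10)
    mine <- seabedmp:::points_in_polygon(px, py, ring)
    bnd <- list(x = ring[-nrow(ring), 1], y = ring[-nrow(ring), 2])
    theirs <- mgcv::in.out(cbind(bnd$x, bnd$y), cbind(px, py))
    expect_equal(mine, as.logical(theirs))
  }
})

test_that("layer summaries classify polygon means and normalize percentages", {
  surf <- toy_surface(c(500, 1500, 2500), nx = 3)
  polys <- list(square_ring(0, 0, 1 / 3, 1), square_ring(1 / 3, 0, 2 / 3, 1),
                square_ring(2 / 3, 0, 1, 1))
  ly <- risk_layer("MPA", "receptor", polys)
  s <- summarize_layer(surf, ly)
  expect_equal(unname(s$percentages),
               c(100 / 3, 100 / 3, 100 / 3, 0))
  expect_equal(sum(s$percentages), 100)
  expect_equal(s$per_polygon$bin,
               c("low", "moderately_elevated", "elevated"))

  ly_far <- risk_layer("far", "receptor", list(square_ring(9, 9, 10, 10)))
  s2 <- summarize_layer(surf, ly_far)
  expect_equal(s2$n_classified, 0)
  expect_equal(s2$n_no_data, 1)
  expect_true(all(is.na(s2$percentages)))
})

test_that("summaries equal the brute-force composition on random pairs", {
  set.seed(21)
  for (rep in 1:10) {
    g <- generate_prediction_grid(nx = 10, ny = 10, bbox = c(0, 10, 0, 10),
                                  predictor_names = "p1", seed = rep)
    surf <- toy_surface(runif(100, 0, 4000), nx = 10, bbox = c(0, 10, 0, 10))
    layers <- generate_risk_layers(c(L = "receptor"), 4,
                                   bbox = c(0, 10, 0, 10), seed = 100 + rep)
    s <- summarize_layer(surf, layers[[1]])
    pm <- polygon_mean_exposure(surf, layers[[1]])
    keep <- !is.na(pm$mean_value)
    tally <- table(factor(as.character(
      classify_abundance(pmax(pm$mean_value[keep], 0))),
      levels = abundance_bins()))
    expected <- 100 * as.numeric(tally) / sum(keep)
    if (sum(keep) > 0) {
      expect_equal(unname(s$percentages), expected)
      expect_equal(sum(s$percentages), 100)
    } else {
      expect_true(all(is.na(s$percentages)))
    }
  }
})

test_that("co-occurrence profiles weight exposure by receptor abundance", {
  surf <- toy_surface(c(10, 20, 30, 40), nx = 2)
  rec_uniform <- data.frame(cell_id = surf$cell_id, value = 1)
  expect_equal(cooccurrence_profile(surf, rec_uniform)$weighted_mean_exposure,
               mean(surf$value))
  rec_point <- data.frame(cell_id = surf$cell_id, value = c(0, 0, 1, 0))
  prof <- cooccurrence_profile(surf, rec_point)
  expect_equal(prof$weighted_mean_exposure, 30)
  expect_equal(prof$n_occupied, 1)
  rec_hand <- data.frame(cell_id = surf$cell_id, value = c(1, 1, 2, 0))
  # (10*1 + 20*1 + 30*2) / 4 = 22.5 by hand
  expect_equal(cooccurrence_profile(surf, rec_hand)$weighted_mean_exposure,
               22.5)
  expect_error(cooccurrence_profile(surf, rec_hand[1:3, ]), "cell_ids")
})
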
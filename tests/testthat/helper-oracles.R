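# Independent oracles and small fixture builders used across the suite.

# Exhaustive stump search: every (feature, midpoint-between-distinct-values)
# candidate, both sides >= minobs, maximizing SSE reduction; ties broken by
# (lowest feature, lowest threshold). Deliberately written as a plain double
# loop, independent of the package's split scan.
brute_force_stump <- function(X, y, minobs = 1) {
  n <- nrow(X)
  s <- sum(y)
  base <- s^2 / n
  best <- list(gain = 0, feature = NA_integer_, threshold = NA_real_,
               left_value = NA_real_, right_value = NA_real_)
  if (min(y) == max(y)) return(best)
  for (f in seq_len(ncol(X))) {
    xs <- sort(unique(X[, f]))
    if (length(xs) < 2) next
    for (i in seq_len(length(xs) - 1)) {
      thr <- xs[i] + (xs[i + 1] - xs[i]) / 2
      l <- X[, f] <= thr
      nl <- sum(l); nr <- n - nl
      if (nl < minobs || nr < minobs) next
      gain <- sum(y[l])^2 / nl + sum(y[!l])^2 / nr - base
      if (gain > best$gain) {
        best <- list(gain = gain, feature = f, threshold = thr,
                     left_value = mean(y[l]), right_value = mean(y[!l]))
      }
    }
  }
  best
}

# evaluate one node-matrix tree on a data matrix (plain R traversal)
eval_tree_r <- function(nodes, X) {
  vapply(seq_len(nrow(X)), function(i) {
    k <- 1
    while (nodes[k, 1] >= 0) {
      f <- nodes[k, 1] + 1
      k <- if (X[i, f] <= nodes[k, 2]) nodes[k, 3] + 1 else nodes[k, 4] + 1
    }
    nodes[k, 5]
  }, numeric(1))
}

# small random regression fixture with continuous features (no ties)
random_instance <- function(n, p, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
  y <- rnorm(n, sd = 2)
  list(X = X, y = y)
}

# a station table with a strong single-step signal on x1 and inert extras
step_table <- function(n = 24, a = 100, b = 50, thr = 0, seed = 1, p_extra = 2) {
  set.seed(seed)
  x1 <- rnorm(n)
  df <- data.frame(x1 = x1)
  for (k in seq_len(p_extra)) df[[paste0("z", k)]] <- rnorm(n)
  df$mp_count <- a + b * (x1 > thr)
  df
}

# generating model used for the recovery experiments: five informative
# predictors with comparable strong effects and gaussian noise calibrated so
# sd(signal) / sd(noise) is about 3.7
recovery_spec <- function(noise_scale = 200) {
  true_model_spec(
    informative_set = default_predictors()[1:5],
    component_functions = list(
      salinity_range        = function(x) 800 * stats::plogis(2 * x),
      wave_orbital_velocity = function(x) 700 * (x > 0),
      silt_pct              = function(x) 650 * pmax(x, 0),
      seafloor_curvature    = function(x) 600 * tanh(1.5 * x),
      nitrogen_content      = function(x) 550 * (x > -0.3)
    ),
    baseline = 600, noise_family = "gaussian", noise_scale = noise_scale
  )
}

# grid + constant-value surface builders for overlay tests
toy_surface <- function(values, nx = NULL, bbox = c(0, 1, 0, 1)) {
  if (is.null(nx)) nx <- ceiling(sqrt(length(values)))
  ny <- ceiling(length(values) / nx)
  g <- expand.grid(
    lon = bbox[1] + (seq_len(nx) - 0.5) / nx * (bbox[2] - bbox[1]),
    lat = bbox[3] + (seq_len(ny) - 0.5) / ny * (bbox[4] - bbox[3])
  )
  g <- g[seq_along(values), ]
  out <- data.frame(cell_id = sprintf("C%04d", seq_along(values)),
                    lon = g$lon, lat = g$lat, value = values,
                    stringsAsFactors = FALSE)
  class(out) <- c("prediction_surface", "data.frame")
  out
}

square_ring <- function(x0, y0, x1, y1) {
  cbind(lon = c(x0, x1, x1, x0, x0), lat = c(y0, y0, y1, y1, y0))
}
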
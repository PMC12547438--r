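#' Default seabed predictor names
#'
#' Ten candidate predictors: five with documented effects in the default
#' generating model (salinity range, wave orbital velocity at the seabed,
#' percent silt, seafloor curvature, nitrogen content) and five placeholders
#' for further physical covariates. The names are configuration, not
#' semantics: the generator treats every predictor as a standardized score.
#'
#' @return character vector of length 10.
#' @export
default_predictors <- function() {
  c("salinity_range", "wave_orbital_velocity", "silt_pct",
    "seafloor_curvature", "nitrogen_content",
    "bottom_current", "grain_size_median", "depth",
    "distance_to_coast", "organic_carbon")
}

#' Specification of a true generating model for synthetic surveys
#'
#' Describes the deterministic part of the response (a baseline plus a sum
#' of per-predictor component functions over the informative predictors, in
#' particles per kg dry-weight sediment) and the noise family layered on top.
#'
#' @param informative_set names of the predictors that truly affect the
#'   response; must be a subset of the predictor names passed to
#'   [generate_station_dataset()].
#' @param component_functions named list of one-argument functions, one per
#'   informative predictor, returning the additive effect in particles/kg.
#' @param baseline non-negative intercept (particles/kg).
#' @param noise_family one of `"none"`, `"gaussian"`, `"negative_binomial"`.
#' @param noise_scale for gaussian noise the standard deviation
#'   (particles/kg); for negative-binomial noise the dispersion size
#'   parameter (variance = mu + mu^2 / size).
#' @return an object of class `true_model_spec`.
#' @examples
#' spec <- true_model_spec(
#'   informative_set = "silt_pct",
#'   component_functions = list(silt_pct = function(x) 500 * pmax(x, 0)),
#'   baseline = 800, noise_family = "gaussian", noise_scale = 100
#' )
#' @export
true_model_spec <- function(informative_set, component_functions,
                            baseline = 600,
                            noise_family = c("negative_binomial", "gaussian",
                                             "none"),
                            noise_scale = 2) {
  noise_family <- match.arg(noise_family)
  informative_set <- as.character(informative_set)
  if (length(informative_set) > 0) {
    if (!is.list(component_functions) ||
        !all(informative_set %in% names(component_functions)))
      stop("component_functions must name a function for every informative predictor")
    stopifnot(all(vapply(component_functions[informative_set], is.function,
                         logical(1))))
  }
  if (!is.numeric(baseline) || baseline < 0) stop("baseline must be >= 0")
  if (!is.numeric(noise_scale) || noise_scale < 0)
    stop("noise_scale must be >= 0")
  structure(list(informative_set = informative_set,
                 component_functions = component_functions,
                 baseline = baseline, noise_family = noise_family,
                 noise_scale = noise_scale),
            class = "true_model_spec")
}

#' Default generating model for synthetic seabed surveys
#'
#' Five informative predictors with smooth-monotone or step effects sized so
#' that, with negative-binomial noise (size 2), the simulated counts span
#' roughly the 0 to ~7000 particles/kg range reported for UK shelf sediment
#' surveys, with strong overdispersion (coefficient of variation around 0.7).
#'
#' @return a `true_model_spec`.
#' @export
default_true_model <- function() {
  true_model_spec(
    informative_set = default_predictors()[1:5],
    component_functions = list(
      salinity_range        = function(x) 900 * stats::plogis(2 * x),
      wave_orbital_velocity = function(x) 700 * (x > 0.25),
      silt_pct              = function(x) 550 * pmax(x, 0),
      seafloor_curvature    = function(x) 450 * tanh(x),
      nitrogen_content      = function(x) 350 * (x > -0.5)
    ),
    baseline = 600, noise_family = "negative_binomial", noise_scale = 2
  )
}

#' Deterministic mean response of a generating model
#'
#' Evaluates `baseline + sum of component functions`, truncated at zero,
#' for each row of a predictor table. Used both inside the generator and as
#' the closed-form reference in tests.
#'
#' @param spec a `true_model_spec`.
#' @param table data frame holding the informative predictor columns.
#' @return numeric vector of non-negative mean responses (particles/kg).
#' @export
evaluate_true_mean <- function(spec, table) {
  stopifnot(inherits(spec, "true_model_spec"))
  mu <- rep(spec$baseline, nrow(table))
  for (nm in spec$informative_set) {
    if (!nm %in% names(table))
      stop("informative predictor not present in table: ", nm)
    mu <- mu + spec$component_functions[[nm]](table[[nm]])
  }
  pmax(mu, 0)
}

# default survey extent: a UK-shelf-sized lon/lat box
default_bbox <- function() {
  c(lon_min = -10, lon_max = 2, lat_min = 49, lat_max = 61)
}

check_bbox <- function(bbox) {
  stopifnot(is.numeric(bbox), length(bbox) == 4)
  names(bbox) <- c("lon_min", "lon_max", "lat_min", "lat_max")
  if (bbox["lon_max"] <= bbox["lon_min"] || bbox["lat_max"] <= bbox["lat_min"])
    stop("degenerate bbox: zero or negative width/height")
  bbox
}

#' Generate a synthetic station survey
#'
#' Draws `n` stations scattered around `cluster_count` cluster centres inside
#' `bbox` (gaussian scatter, emulating the close spacing of repeat-visit
#' survey stations), i.i.d. standard-normal predictor scores, and a
#' microplastic count response `mp_count = baseline + sum of component
#' effects + noise`, truncated at zero.
#'
#' @param n number of stations (>= 2).
#' @param predictor_names candidate predictor columns to simulate; must
#'   contain `spec$informative_set`.
#' @param spec a [true_model_spec()]; defaults to [default_true_model()].
#' @param cluster_count number of spatial clusters.
#' @param seed integer master seed; the output is reproducible given it.
#' @param bbox survey extent `c(lon_min, lon_max, lat_min, lat_max)` in
#'   decimal degrees (WGS84).
#' @param cluster_sd gaussian scatter of stations about their cluster centre
#'   (degrees).
#' @return list with `stations` (data frame: `station_id`, `lon`, `lat`, one
#'   column per predictor, `mp_count`) and `spec` (the generating model).
#' @examples
#' sim <- generate_station_dataset(n = 56, seed = 7)
#' dim(sim$stations)
#' @export
generate_station_dataset <- function(n = 56, predictor_names = default_predictors(),
                                     spec = default_true_model(),
                                     cluster_count = 5, seed = 1,
                                     bbox = default_bbox(), cluster_sd = 0.3) {
  stopifnot(inherits(spec, "true_model_spec"))
  if (n < 2) stop("n must be >= 2")
  if (cluster_count < 1) stop("cluster_count must be >= 1")
  bbox <- check_bbox(bbox)
  bad <- setdiff(spec$informative_set, predictor_names)
  if (length(bad) > 0)
    stop("informative predictors not in predictor_names: ",
         paste(bad, collapse = ", "))

  set.seed(derive_seed(seed, 11L))
  centres_lon <- runif(cluster_count, bbox["lon_min"], bbox["lon_max"])
  centres_lat <- runif(cluster_count, bbox["lat_min"], bbox["lat_max"])
  assign <- sample.int(cluster_count, n, replace = TRUE)
  lon <- pmin(pmax(centres_lon[assign] + rnorm(n, 0, cluster_sd),
                   bbox["lon_min"]), bbox["lon_max"])
  lat <- pmin(pmax(centres_lat[assign] + rnorm(n, 0, cluster_sd),
                   bbox["lat_min"]), bbox["lat_max"])

  p <- length(predictor_names)
  X <- matrix(rnorm(n * p), nrow = n, ncol = p,
              dimnames = list(NULL, predictor_names))
  tbl <- as.data.frame(X)
  mu <- evaluate_true_mean(spec, tbl)

  set.seed(derive_seed(seed, 12L))
  mp <- switch(spec$noise_family,
    none = mu,
    gaussian = pmax(mu + rnorm(n, 0, spec$noise_scale), 0),
    negative_binomial = as.numeric(rnbinom(n, size = spec$noise_scale,
                                           mu = mu))
  )
  stations <- cbind(
    data.frame(station_id = sprintf("ST%04d", seq_len(n)),
               lon = as.numeric(lon), lat = as.numeric(lat),
               stringsAsFactors = FALSE),
    tbl
  )
  stations$mp_count <- mp
  list(stations = stations, spec = spec)
}

#' Generate a prediction grid with smooth synthetic predictor surfaces
#'
#' Lays out an `nx` by `ny` grid of cell centres over `bbox` and attaches one
#' smooth random field per predictor, built from a low-rank random cosine
#' basis (each field is a sum of `n_basis` cosines with random frequencies up
#' to `1/smoothness` in normalized coordinates, standardized to unit
#' variance). Deterministic for a fixed seed.
#'
#' @param nx,ny number of cells along longitude and latitude (>= 1).
#' @param bbox grid extent `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param predictor_names predictor columns to synthesize.
#' @param smoothness spatial length scale of the fields as a fraction of the
#'   bbox extent; larger is smoother.
#' @param seed integer seed.
#' @param n_basis number of cosine components per field.
#' @return data frame with `cell_id`, `lon`, `lat` and one column per
#'   predictor; attribute `bbox` carries the extent.
#' @examples
#' g <- generate_prediction_grid(nx = 5, ny = 4, seed = 3)
#' nrow(g)  # 20
#' @export
generate_prediction_grid <- function(nx = 20, ny = 20, bbox = default_bbox(),
                                     predictor_names = default_predictors(),
                                     smoothness = 0.3, seed = 1,
                                     n_basis = 12) {
  if (nx < 1 || ny < 1) stop("nx and ny must be >= 1")
  if (smoothness <= 0) stop("smoothness must be > 0")
  bbox <- check_bbox(bbox)
  # cell centres
  lon <- bbox["lon_min"] + (seq_len(nx) - 0.5) / nx *
    (bbox["lon_max"] - bbox["lon_min"])
  lat <- bbox["lat_min"] + (seq_len(ny) - 0.5) / ny *
    (bbox["lat_max"] - bbox["lat_min"])
  cells <- expand.grid(lon = lon, lat = lat, KEEP.OUT.ATTRS = FALSE)
  u <- (cells$lon - bbox["lon_min"]) / (bbox["lon_max"] - bbox["lon_min"])
  v <- (cells$lat - bbox["lat_min"]) / (bbox["lat_max"] - bbox["lat_min"])

  out <- data.frame(cell_id = sprintf("C%05d", seq_len(nrow(cells))),
                    lon = cells$lon, lat = cells$lat,
                    stringsAsFactors = FALSE)
  fmax <- 1 / smoothness
  for (k in seq_along(predictor_names)) {
    set.seed(derive_seed(seed, 21L, k))
    amp <- rnorm(n_basis)
    w1 <- runif(n_basis, -fmax, fmax)
    w2 <- runif(n_basis, -fmax, fmax)
    phase <- runif(n_basis, 0, 2 * pi)
    f <- rep(0, nrow(cells))
    for (b in seq_len(n_basis))
      f <- f + amp[b] * cos(2 * pi * (w1[b] * u + w2[b] * v) + phase[b])
    # each cosine has variance 1/2 over a uniform phase, so the sum of
    # n_basis independent components is standardized by sqrt(n_basis / 2)
    out[[predictor_names[k]]] <- f / sqrt(n_basis / 2)
  }
  attr(out, "bbox") <- bbox
  out
}

#' A single source/receptor polygon layer
#'
#' @param name layer name (e.g. `"MPA"`, `"disposal_sites"`).
#' @param kind `"source"` (activity adding microlitter) or `"receptor"`
#'   (asset at risk from it).
#' @param polygons list of closed lon/lat rings: two-column matrices whose
#'   last vertex repeats the first.
#' @return an object of class `risk_layer`.
#' @export
risk_layer <- function(name, kind, polygons) {
  kind <- match.arg(kind, c("source", "receptor"))
  stopifnot(is.list(polygons))
  polygons <- lapply(polygons, function(ring) {
    ring <- as.matrix(ring)
    stopifnot(ncol(ring) == 2, nrow(ring) >= 4)
    if (!isTRUE(all.equal(ring[1, ], ring[nrow(ring), ], check.attributes = FALSE)))
      stop("polygon ring must be closed (first vertex repeated last)")
    colnames(ring) <- c("lon", "lat")
    ring
  })
  structure(list(name = as.character(name), kind = kind, polygons = polygons),
            class = "risk_layer")
}

#' @export
print.risk_layer <- function(x, ...) {
  cat("Risk layer '", x$name, "' (", x$kind, "): ",
      length(x$polygons), " polygon(s)\n", sep = "")
  invisible(x)
}

#' Generate random convex source/receptor polygon layers
#'
#' For each named category, draws `polygons_per_kind` convex polygons (convex
#' hulls of random points in a disc) fully inside `bbox`, tagged with the
#' layer name and its kind.
#'
#' @param kinds named character vector mapping layer name to kind, e.g.
#'   `c(MPA = "receptor", disposal_sites = "source")`. An empty vector yields
#'   an empty list.
#' @param polygons_per_kind polygons per layer (>= 1).
#' @param bbox extent the polygons must stay inside.
#' @param seed integer seed.
#' @param n_vertices random points per polygon before taking the hull.
#' @return list of [risk_layer()] objects.
#' @examples
#' layers <- generate_risk_layers(c(MPA = "receptor"), 3, seed = 2)
#' @export
generate_risk_layers <- function(kinds, polygons_per_kind = 3,
                                 bbox = default_bbox(), seed = 1,
                                 n_vertices = 8) {
  if (length(kinds) == 0) return(list())
  if (is.null(names(kinds)) || any(names(kinds) == ""))
    stop("kinds must be a named vector: name -> source/receptor")
  if (polygons_per_kind < 1) stop("polygons_per_kind must be >= 1")
  bbox <- check_bbox(bbox)
  span_lon <- bbox["lon_max"] - bbox["lon_min"]
  span_lat <- bbox["lat_max"] - bbox["lat_min"]

  out <- vector("list", length(kinds))
  for (k in seq_along(kinds)) {
    polys <- vector("list", polygons_per_kind)
    for (j in seq_len(polygons_per_kind)) {
      set.seed(derive_seed(seed, 31L, k, j))
      r_max <- 0.12 * min(span_lon, span_lat)
      r <- runif(1, 0.4 * r_max, r_max)
      cx <- runif(1, bbox["lon_min"] + r_max, bbox["lon_max"] - r_max)
      cy <- runif(1, bbox["lat_min"] + r_max, bbox["lat_max"] - r_max)
      ang <- runif(n_vertices, 0, 2 * pi)
      rad <- r * sqrt(runif(n_vertices))
      px <- cx + rad * cos(ang)
      py <- cy + rad * sin(ang)
      hull <- grDevices::chull(px, py)
      ring <- cbind(lon = px[hull], lat = py[hull])
      ring <- rbind(ring, ring[1, , drop = FALSE])
      polys[[j]] <- ring
    }
    out[[k]] <- risk_layer(names(kinds)[k], kinds[[k]], polys)
  }
  out
}

#' Spatial covariance specification for synthetic residual fields
#'
#' @param range_km range of the exponential covariance (km, > 0).
#' @param sill partial sill (variance units, >= 0).
#' @param nugget nugget variance (>= 0).
#' @return an object of class `spatial_field_spec`.
#' @export
spatial_field_spec <- function(range_km, sill = 1, nugget = 0) {
  if (!is.numeric(range_km) || range_km <= 0) stop("range_km must be > 0")
  if (!is.numeric(sill) || sill < 0) stop("sill must be >= 0")
  if (!is.numeric(nugget) || nugget < 0) stop("nugget must be >= 0")
  structure(list(range_km = range_km, sill = sill, nugget = nugget),
            class = "spatial_field_spec")
}

#' Simulate a zero-mean gaussian field with exponential covariance
#'
#' Draws one realization at the supplied coordinates from a multivariate
#' normal with covariance `sill * exp(-d / range_km)` plus `nugget` on the
#' diagonal, `d` being pairwise great-circle (or planar) distance in km.
#' Used to exercise the semivariogram diagnostics on fields with known
#' spatial structure.
#'
#' @param coords two-column matrix/data frame of lon/lat (or planar x/y in
#'   km when `distance = "euclidean"`), at least two rows.
#' @param spec a [spatial_field_spec()].
#' @param seed integer seed.
#' @param distance `"haversine"` (great-circle on lon/lat) or `"euclidean"`.
#' @return numeric vector, one value per coordinate.
#' @export
generate_spatial_residual_field <- function(coords, spec, seed = 1,
                                            distance = c("haversine",
                                                         "euclidean")) {
  stopifnot(inherits(spec, "spatial_field_spec"))
  distance <- match.arg(distance)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2) stop("need at least two coordinates")
  D <- pairwise_distances_km(coords, distance)
  Sigma <- spec$sill * exp(-D / spec$range_km) + diag(spec$nugget, n)
  R <- tryCatch(chol(Sigma), error = function(e) {
    tryCatch(chol(Sigma + diag(1e-8 * max(spec$sill + spec$nugget, 1), n)),
             error = function(e2)
               stop("covariance matrix not positive definite after jitter"))
  })
  set.seed(derive_seed(seed, 41L))
  as.numeric(crossprod(R, rnorm(n)))
}
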
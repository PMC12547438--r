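# pairwise distance matrix in km; haversine on lon/lat (WGS84) for survey
# coordinates, plain euclidean for synthetic planar fixtures already in km
pairwise_distances_km <- function(coords, distance = c("haversine",
                                                       "euclidean")) {
  distance <- match.arg(distance)
  coords <- as.matrix(coords)
  if (distance == "haversine") {
    geosphere::distm(coords, fun = geosphere::distHaversine) / 1000
  } else {
    as.matrix(stats::dist(coords))
  }
}

#' Residuals of a boosted model on a station table
#'
#' `observed - predicted`, in table row order (particles/kg).
#'
#' @param model a `boosted_model`.
#' @param table station data frame with the model features and the response.
#' @param response_name response column.
#' @return numeric vector of residuals.
#' @export
model_residuals <- function(model, table, response_name = "mp_count") {
  if (!response_name %in% names(table))
    stop("response column not found: ", response_name)
  as.numeric(table[[response_name]]) - predict(model, table)
}

#' Empirical semivariogram (Matheron estimator)
#'
#' Bins all point pairs by separation distance into `n_bins` equal-width
#' bins up to `max_dist` and computes, per bin, half the mean squared
#' difference of values:
#' `gamma(h) = (1 / (2 |N(h)|)) * sum over pairs in bin of (z_i - z_j)^2`.
#' A flat curve at the sample variance indicates no spatial autocorrelation;
#' a rise over distance indicates positive correlation at short range.
#'
#' @param coords two-column lon/lat matrix or data frame (or planar km with
#'   `distance = "euclidean"`).
#' @param values numeric vector, one value per coordinate (e.g. model
#'   residuals).
#' @param n_bins number of distance bins (>= 1).
#' @param max_dist maximum pair distance considered (km). Defaults to half
#'   the maximum pairwise distance, a standard variography convention.
#' @param distance `"haversine"` or `"euclidean"`.
#' @return object of class `semivariogram`: data frame with `bin_lower`,
#'   `bin_upper`, `bin_center` (km), `semivariance` (`NA` in empty bins) and
#'   `pair_count`.
#' @examples
#' co <- cbind(lon = runif(30, -4, 0), lat = runif(30, 50, 53))
#' sv <- empirical_semivariogram(co, rnorm(30), n_bins = 5)
#' @export
empirical_semivariogram <- function(coords, values, n_bins = 10,
                                    max_dist = NULL,
                                    distance = c("haversine", "euclidean")) {
  distance <- match.arg(distance)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2) stop("need at least two points")
  if (length(values) != n) stop("coords and values lengths differ")
  if (n_bins < 1) stop("n_bins must be >= 1")
  D <- pairwise_distances_km(coords, distance)
  iu <- which(upper.tri(D), arr.ind = TRUE)
  d <- D[iu]
  sq <- (values[iu[, 1]] - values[iu[, 2]])^2
  if (is.null(max_dist)) max_dist <- max(d) / 2
  if (max_dist <= 0) stop("max_dist must be > 0")

  edges <- seq(0, max_dist, length.out = n_bins + 1)
  keep <- d <= max_dist
  bin <- pmin(pmax(ceiling(d[keep] / (max_dist / n_bins)), 1L), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  sums <- vapply(seq_len(n_bins), function(b) sum(sq[keep][bin == b]),
                 numeric(1))
  gamma <- ifelse(counts > 0, sums / (2 * counts), NA_real_)
  out <- data.frame(bin_lower = edges[-(n_bins + 1)], bin_upper = edges[-1],
                    bin_center = (edges[-(n_bins + 1)] + edges[-1]) / 2,
                    semivariance = gamma, pair_count = counts)
  attr(out, "max_dist") <- max_dist
  attr(out, "distance") <- distance
  class(out) <- c("semivariogram", "data.frame")
  out
}

#' Monte-Carlo permutation envelope for a semivariogram
#'
#' Re-computes the binned semivariance after randomly permuting the values
#' over the locations `n_perm` times (destroying any spatial structure while
#' keeping the marginal distribution), and returns per-bin lower/upper
#' quantiles. An observed curve escaping the envelope suggests spatial
#' autocorrelation; the function reports the envelope and makes no pass/fail
#' claim.
#'
#' @inheritParams empirical_semivariogram
#' @param n_perm number of permutations (199 by default).
#' @param probs two quantile levels for the envelope.
#' @param seed integer seed for the permutations.
#' @return data frame: the observed semivariogram plus `envelope_lower` and
#'   `envelope_upper` columns.
#' @export
semivariogram_envelope <- function(coords, values, n_bins = 10,
                                   max_dist = NULL,
                                   distance = c("haversine", "euclidean"),
                                   n_perm = 199, probs = c(0.025, 0.975),
                                   seed = 1) {
  distance <- match.arg(distance)
  obs <- empirical_semivariogram(coords, values, n_bins, max_dist, distance)
  md <- attr(obs, "max_dist")
  perms <- matrix(NA_real_, nrow = n_perm, ncol = n_bins)
  for (r in seq_len(n_perm)) {
    set.seed(derive_seed(seed, 701L, r))
    v <- values[sample.int(length(values))]
    perms[r, ] <- empirical_semivariogram(coords, v, n_bins, md,
                                          distance)$semivariance
  }
  obs$envelope_lower <- apply(perms, 2, quantile, probs = probs[1],
                              na.rm = TRUE, names = FALSE)
  obs$envelope_upper <- apply(perms, 2, quantile, probs = probs[2],
                              na.rm = TRUE, names = FALSE)
  obs
}
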
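#' Project a boosted model onto a prediction grid
#'
#' Evaluates the model at every grid cell. The resulting surface is a
#' unitless relative storage-potential score (no rescaling is applied by
#' default; see `rescale_range`).
#'
#' @param model a `boosted_model`.
#' @param grid data frame with `cell_id`, `lon`, `lat` and every model
#'   feature (see [generate_prediction_grid()]).
#' @param rescale_range optional length-2 numeric: affinely map the surface
#'   onto `[rescale_range[1], rescale_range[2]]`. Off (`NULL`) by default;
#'   the score is relative and a particles/kg reading of it is a user
#'   decision, not a model output.
#' @return object of class `prediction_surface`: data frame `cell_id`,
#'   `lon`, `lat`, `value`.
#' @export
predict_surface <- function(model, grid, rescale_range = NULL) {
  needed <- c("cell_id", "lon", "lat")
  if (!all(needed %in% names(grid)))
    stop("grid must have columns cell_id, lon, lat")
  if (anyDuplicated(grid$cell_id)) stop("cell_ids must be unique")
  value <- predict(model, grid)
  if (!is.null(rescale_range)) {
    stopifnot(length(rescale_range) == 2, rescale_range[1] < rescale_range[2])
    rng <- range(value)
    value <- if (rng[2] > rng[1]) {
      rescale_range[1] + (value - rng[1]) / (rng[2] - rng[1]) *
        (rescale_range[2] - rescale_range[1])
    } else {
      rep(mean(rescale_range), length(value))
    }
  }
  out <- data.frame(cell_id = grid$cell_id, lon = grid$lon, lat = grid$lat,
                    value = value, stringsAsFactors = FALSE)
  class(out) <- c("prediction_surface", "data.frame")
  out
}

#' Abundance exposure bins
#'
#' The four bands used to classify mean microplastic abundance, in
#' particles per kg dry-weight sediment.
#'
#' @return ordered factor levels `low < moderately_elevated < elevated <
#'   highly_elevated`.
#' @export
abundance_bins <- function() {
  c("low", "moderately_elevated", "elevated", "highly_elevated")
}

#' Classify abundance values into exposure bins
#'
#' Band edges follow the integer bands 0-1000 (low), 1001-2000 (moderately
#' elevated), 2001-3000 (elevated), above 3001 (highly elevated); for
#' real-valued inputs the half-open convention `[0, 1000] (1000, 2000]
#' (2000, 3000] (3000, Inf)` is used, so e.g. 1000 is low and 3000.5 is
#' highly elevated.
#'
#' @param value numeric vector of non-negative abundances (particles/kg).
#' @param thresholds strictly increasing upper bounds of the first three
#'   bands (particles/kg).
#' @return ordered factor over [abundance_bins()].
#' @examples
#' classify_abundance(c(0, 1000, 1001, 2700, 3000.5))
#' @export
classify_abundance <- function(value, thresholds = c(1000, 2000, 3000)) {
  value <- as.numeric(value)
  if (any(!is.finite(value))) stop("abundance values must be finite")
  if (any(value < 0)) stop("abundance values must be >= 0")
  stopifnot(length(thresholds) == 3, !is.unsorted(thresholds, strictly = TRUE))
  cut(value, breaks = c(0, thresholds, Inf), labels = abundance_bins(),
      include.lowest = TRUE, right = TRUE, ordered_result = TRUE)
}

#' Mean predicted exposure inside each polygon of a layer
#'
#' A grid cell belongs to a polygon when its centre falls inside the polygon
#' ring (boundary counts as inside). Polygons containing no cell centre get
#' a no-data flag (`NA` mean).
#'
#' @param surface a [predict_surface()] result.
#' @param layer a [risk_layer()].
#' @return data frame with `polygon_id`, `n_cells`, `mean_value` (`NA` when
#'   no cell centre falls inside).
#' @export
polygon_mean_exposure <- function(surface, layer) {
  stopifnot(inherits(layer, "risk_layer"))
  if (nrow(surface) < 1) stop("surface is empty")
  out <- lapply(seq_along(layer$polygons), function(j) {
    ring <- layer$polygons[[j]]
    if (!ring_is_simple(ring))
      stop("polygon ", j, " of layer '", layer$name, "' is not simple")
    inside <- points_in_polygon(surface$lon, surface$lat, ring)
    data.frame(polygon_id = sprintf("%s_%03d", layer$name, j),
               n_cells = sum(inside),
               mean_value = if (any(inside)) mean(surface$value[inside])
                            else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Exposure summary of a risk layer
#'
#' Classifies each polygon's mean predicted abundance into the exposure
#' bins and reports, over the classified (non-no-data) polygons, the
#' percentage falling in each bin (full precision; they sum to 100).
#' Polygons without any grid-cell centre are counted separately as no-data.
#'
#' @inheritParams polygon_mean_exposure
#' @param thresholds band edges passed to [classify_abundance()].
#' @return object of class `layer_exposure_summary`: list with `layer`,
#'   `kind`, `per_polygon` (means and bins), `percentages` (named numeric
#'   over bins), `n_classified`, `n_no_data`.
#' @export
summarize_layer <- function(surface, layer, thresholds = c(1000, 2000, 3000)) {
  per_polygon <- polygon_mean_exposure(surface, layer)
  classified <- !is.na(per_polygon$mean_value)
  bins <- rep(NA_character_, nrow(per_polygon))
  if (any(classified)) {
    # exposure bands are defined on non-negative abundances; a relative
    # surface can dip below zero, which clamps to the lowest band
    bins[classified] <-
      as.character(classify_abundance(pmax(per_polygon$mean_value[classified],
                                           0), thresholds))
  }
  per_polygon$bin <- bins
  counts <- table(factor(bins[classified], levels = abundance_bins()))
  n_cl <- sum(classified)
  percentages <- if (n_cl > 0) 100 * as.numeric(counts) / n_cl
                 else rep(NA_real_, length(abundance_bins()))
  names(percentages) <- abundance_bins()
  structure(list(layer = layer$name, kind = layer$kind,
                 per_polygon = per_polygon, percentages = percentages,
                 n_classified = n_cl,
                 n_no_data = sum(!classified)),
            class = "layer_exposure_summary")
}

#' @export
print.layer_exposure_summary <- function(x, ...) {
  cat("Layer '", x$layer, "' (", x$kind, "): ", x$n_classified,
      " classified polygon(s), ", x$n_no_data, " no-data\n", sep = "")
  if (x$n_classified > 0) {
    pct <- round(x$percentages)
    for (b in names(pct))
      cat(sprintf("  %-20s %3d%%\n", b, pct[[b]]))
  }
  invisible(x)
}

#' Co-occurrence profile of predicted exposure and a receptor abundance
#'
#' Quantitative companion to overlaying a receptor abundance surface (e.g. a
#' benthic species distribution) on the predicted microlitter surface:
#' the receptor-abundance-weighted mean exposure, plus quantiles of exposure
#' over the cells the receptor occupies (weight > 0).
#'
#' @param surface a `prediction_surface` (exposure).
#' @param receptor data frame with `cell_id` and `value` (non-negative
#'   receptor abundance) over the same cell set.
#' @param probs quantile levels for the occupied-cell exposure summary.
#' @return list with `weighted_mean_exposure`, `occupied_quantiles`,
#'   `n_occupied`.
#' @export
cooccurrence_profile <- function(surface, receptor,
                                 probs = c(0.05, 0.25, 0.5, 0.75, 0.95)) {
  if (!all(c("cell_id", "value") %in% names(receptor)))
    stop("receptor must have columns cell_id and value")
  if (!setequal(surface$cell_id, receptor$cell_id) ||
      nrow(surface) != nrow(receptor))
    stop("surface and receptor must share the same cell_ids")
  w <- receptor$value[match(surface$cell_id, receptor$cell_id)]
  if (any(!is.finite(w)) || any(w < 0))
    stop("receptor abundance must be finite and >= 0")
  if (sum(w) <= 0) stop("receptor abundance is zero everywhere")
  occupied <- w > 0
  list(weighted_mean_exposure = sum(w * surface$value) / sum(w),
       occupied_quantiles = quantile(surface$value[occupied], probs = probs,
                                     names = TRUE),
       n_occupied = sum(occupied))
}
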
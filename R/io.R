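# CSV dialect everywhere: comma-separated, UTF-8, "." decimal, header
# mandatory. Numeric columns are written with 17 significant digits so a
# write -> read round trip reproduces doubles exactly.

format_numeric_cols <- function(df) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) {
      v <- df[[nm]]
      s <- sprintf("%.17g", v)
      s[is.na(v)] <- NA_character_
      df[[nm]] <- s
    }
  }
  df
}

write_csv_exact <- function(df, path) {
  utils::write.csv(format_numeric_cols(as.data.frame(df)), path,
                   row.names = FALSE, quote = TRUE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a station table to CSV
#'
#' @param stations station data frame (`station_id`, `lon`, `lat`,
#'   predictors, `mp_count`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_station_csv <- function(stations, path) {
  stopifnot(all(c("station_id", "lon", "lat", "mp_count") %in% names(stations)))
  write_csv_exact(stations, path)
}

#' Read a station table from CSV
#'
#' Rows with any missing field are dropped (with a message reporting the
#' count), restricting the analysis to complete observations.
#'
#' @param path CSV file with header `station_id, lon, lat, <predictors...>,
#'   mp_count`.
#' @return station data frame of complete rows.
#' @export
read_station_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8"),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e))
  )
  if (nrow(df) == 0 && ncol(df) == 0) stop("empty station file: ", path)
  needed <- c("station_id", "lon", "lat", "mp_count")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0)
    stop("station file lacks columns: ", paste(missing_cols, collapse = ", "))
  complete <- stats::complete.cases(df) &
    rowSums(as.matrix(df == "") > 0, na.rm = TRUE) == 0
  dropped <- sum(!complete)
  if (dropped > 0)
    message("read_station_csv: dropped ", dropped,
            " incomplete row(s); keeping ", sum(complete))
  df <- df[complete, , drop = FALSE]
  if (nrow(df) == 0) stop("no complete rows in ", path)
  if (anyDuplicated(df$station_id)) stop("duplicate station_ids in ", path)
  for (nm in setdiff(names(df), "station_id")) df[[nm]] <- as.numeric(df[[nm]])
  rownames(df) <- NULL
  df
}

#' Write a prediction grid (or surface) to CSV
#' @param grid data frame with `cell_id`, `lon`, `lat` and value/predictor
#'   columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  stopifnot(all(c("cell_id", "lon", "lat") %in% names(grid)))
  write_csv_exact(grid, path)
}

#' Read a prediction grid from CSV
#' @param path CSV with header `cell_id, lon, lat, <columns...>`.
#' @return data frame.
#' @export
read_grid_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!all(c("cell_id", "lon", "lat") %in% names(df)))
    stop("grid file lacks cell_id/lon/lat columns: ", path)
  for (nm in setdiff(names(df), "cell_id")) df[[nm]] <- as.numeric(df[[nm]])
  df
}

#' Write risk layers as a GeoJSON FeatureCollection
#'
#' One Polygon feature per polygon, properties `{name, kind}`; exterior
#' rings are written counter-clockwise (RFC 7946), coordinates WGS84
#' lon/lat at full precision.
#'
#' @param layers list of [risk_layer()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_layers_geojson <- function(layers, path) {
  features <- list()
  for (layer in layers) {
    stopifnot(inherits(layer, "risk_layer"))
    for (ring in layer$polygons) {
      ring <- ring_ccw(ring)
      coords <- lapply(seq_len(nrow(ring)), function(i) as.numeric(ring[i, ]))
      features[[length(features) + 1]] <- list(
        type = "Feature",
        properties = list(name = layer$name, kind = layer$kind),
        geometry = list(type = "Polygon", coordinates = list(coords))
      )
    }
  }
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read risk layers from a GeoJSON FeatureCollection
#'
#' Polygon features are grouped by their `name` property into one
#' [risk_layer()] per name. `kind` must be `source` or `receptor`; rings
#' must be simple (non-self-intersecting).
#'
#' @param path GeoJSON file.
#' @return list of `risk_layer` objects (in order of first appearance).
#' @export
read_layers_geojson <- function(path) {
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(fc$type, "FeatureCollection"))
    stop("not a GeoJSON FeatureCollection: ", path)
  groups <- list()
  kinds <- character(0)
  for (i in seq_along(fc$features)) {
    ft <- fc$features[[i]]
    nm <- ft$properties$name
    kind <- ft$properties$kind
    if (is.null(nm) || is.null(kind))
      stop("feature ", i, " lacks name/kind properties")
    if (!kind %in% c("source", "receptor"))
      stop("feature ", i, " ('", nm, "'): kind must be source or receptor, got '",
           kind, "'")
    if (!identical(ft$geometry$type, "Polygon"))
      stop("feature ", i, " ('", nm, "'): only Polygon geometries are supported")
    ring_raw <- ft$geometry$coordinates[[1]]
    ring <- do.call(rbind, lapply(ring_raw, function(pt)
      c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))))
    colnames(ring) <- c("lon", "lat")
    if (!ring_is_simple(ring))
      stop("feature ", i, " ('", nm, "'): self-intersecting ring")
    if (!nm %in% names(groups)) {
      groups[[nm]] <- list()
      kinds[nm] <- kind
    } else if (!identical(kinds[[nm]], kind)) {
      stop("layer '", nm, "' mixes source and receptor features")
    }
    groups[[nm]][[length(groups[[nm]]) + 1]] <- ring
  }
  lapply(names(groups), function(nm) risk_layer(nm, kinds[[nm]], groups[[nm]]))
}

#' Write a prediction surface as GeoJSON points
#'
#' @param surface a `prediction_surface`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_surface_geojson <- function(surface, path) {
  features <- lapply(seq_len(nrow(surface)), function(i) list(
    type = "Feature",
    properties = list(cell_id = surface$cell_id[i],
                      value = surface$value[i]),
    geometry = list(type = "Point",
                    coordinates = c(surface$lon[i], surface$lat[i]))
  ))
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a selection report (CSV curve + JSON record)
#'
#' @param curve a [selection_curve()].
#' @param best character vector from [select_best_model()].
#' @param params the [boost_params()] used.
#' @param csv_path,json_path output paths.
#' @return `json_path`, invisibly.
#' @export
write_selection_report <- function(curve, best, params, csv_path, json_path) {
  df <- data.frame(size = seq_along(curve$variable_order),
                   variable_added = curve$variable_order,
                   mean_loomae = curve$mean_loomae,
                   sd_loomae = curve$sd_loomae,
                   stringsAsFactors = FALSE)
  write_csv_exact(df, csv_path)
  rec <- list(variable_order = curve$variable_order,
              mean_loomae_by_size = curve$mean_loomae,
              sd_loomae_by_size = curve$sd_loomae,
              reps = curve$reps,
              selected = best,
              params = unclass(params))
  jsonlite::write_json(rec, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(json_path)
}

#' Write a layer exposure summary (CSV per-polygon table + JSON percentages)
#'
#' @param summary a [summarize_layer()] result.
#' @param csv_path,json_path output paths.
#' @return `json_path`, invisibly.
#' @export
write_layer_summary <- function(summary, csv_path, json_path) {
  stopifnot(inherits(summary, "layer_exposure_summary"))
  write_csv_exact(summary$per_polygon, csv_path)
  rec <- list(layer = summary$layer, kind = summary$kind,
              percentages = as.list(summary$percentages),
              n_classified = summary$n_classified,
              n_no_data = summary$n_no_data)
  jsonlite::write_json(rec, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(json_path)
}
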
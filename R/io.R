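# Plain-text readers/writers for the package's objects: tidy CSV for
# tabular data, GeoJSON for geometries, CSV (row, col, value) for rasters.

#' Read a telemetry CSV
#'
#' Columns `wolf_id`, `timestamp_h`, `x_m`, `y_m` and optionally `month`.
#'
#' @param path File path.
#' @param nominal_interval Nominal fix interval in hours, attached as an
#'   attribute.
#' @return A telemetry tibble.
#' @export
read_telemetry_csv <- function(path, nominal_interval = 2) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("wolf_id", "timestamp_h", "x_m", "y_m")
  if (!all(need %in% names(out))) {
    stop("telemetry CSV needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  attr(out, "nominal_interval") <- nominal_interval
  out
}

#' Write a tibble as CSV
#'
#' Thin wrapper used for telemetry, step series, path statistics, survey
#' results and occupancy curves alike.
#'
#' @param x A data frame.
#' @param path File path.
#' @return `x`, invisibly.
#' @export
write_tidy_csv <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path)
  invisible(x)
}

#' Write a landscape raster as CSV
#'
#' Long format `row`, `col`, `x_m`, `y_m`, `value`; the header carries no
#' metadata, so origin and cell size travel in the coordinate columns.
#'
#' @param raster A `landscape_raster`.
#' @param path File path.
#' @return The raster, invisibly.
#' @export
write_raster_csv <- function(raster, path) {
  readr::write_csv(as_tibble(raster), path)
  invisible(raster)
}

geojson_feature <- function(geometry, properties) {
  list(type = "Feature", properties = properties, geometry = geometry)
}

geojson_write <- function(features, path) {
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Write line features, paths, territories or a grid as GeoJSON
#'
#' Polylines become `LineString` features; territory circles are written
#' as 64-gon `Polygon`s; grid cells as square `Polygon`s with their cell id.
#'
#' @param x A feature tibble, path tibble, `territory_layout` or
#'   `survey_grid`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_geojson <- function(x, path) {
  if (inherits(x, "survey_grid")) {
    feats <- lapply(seq_len(x$n_cells), function(id) {
      col <- (id - 1) %% x$n_x
      row <- (id - 1) %/% x$n_x
      x0 <- x$extent[["xmin"]] + col * x$cell_side_m
      y0 <- x$extent[["ymin"]] + row * x$cell_side_m
      ring <- list(c(x0, y0), c(x0 + x$cell_side_m, y0),
                   c(x0 + x$cell_side_m, y0 + x$cell_side_m),
                   c(x0, y0 + x$cell_side_m), c(x0, y0))
      geojson_feature(list(type = "Polygon", coordinates = list(ring)),
                      list(cell_id = id))
    })
    return(geojson_write(feats, path))
  }
  if (inherits(x, "territory_layout")) {
    ang <- seq(0, 2 * pi, length.out = 65)
    feats <- lapply(seq_len(nrow(x)), function(i) {
      ring <- lapply(ang, function(a) {
        c(x$cx[i] + x$radius_m[i] * cos(a), x$cy[i] + x$radius_m[i] * sin(a))
      })
      geojson_feature(list(type = "Polygon", coordinates = list(ring)),
                      list(pack_id = x$pack_id[i], radius_m = x$radius_m[i]))
    })
    return(geojson_write(feats, path))
  }
  if (is.data.frame(x) && all(c("x_m", "y_m") %in% names(x))) {
    key <- if ("path_id" %in% names(x)) "path_id" else "feature_id"
    feats <- lapply(split(x, x[[key]]), function(df) {
      coords <- lapply(seq_len(nrow(df)), function(i) c(df$x_m[i], df$y_m[i]))
      props <- list(id = df[[key]][1])
      if ("kind" %in% names(df)) props$kind <- df$kind[1]
      if ("owner" %in% names(df)) props$owner <- df$owner[1]
      if ("pack_id" %in% names(df)) props$pack_id <- df$pack_id[1]
      geojson_feature(list(type = "LineString", coordinates = coords), props)
    })
    return(geojson_write(unname(feats), path))
  }
  stop("no GeoJSON writer for this object", call. = FALSE)
}
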
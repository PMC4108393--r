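# Synthetic landscape inputs: habitat-quality (RSF) surfaces, linear
# landscape features, and ground-truth GPS telemetry. These stand in for the
# study system's unpublished empirical inputs; only their *role* (spatial
# bias weight, crossing-target geometry, fit input) matters.

#' Generate a smooth synthetic habitat-quality (RSF) surface
#'
#' A stationary Gaussian random field built by smoothing unit white noise
#' with a normalized Gaussian kernel of the requested correlation length
#' (FFT convolution, periodic boundary), then mapped through the standard
#' normal CDF into habitat weights in (0.05, 1]. The field is *not*
#' re-standardized after smoothing: heavy smoothing shrinks the field
#' toward 0 and therefore the surface toward a constant ~0.525, so
#' `smoothness` genuinely controls both correlation length and contrast.
#'
#' @param extent Numeric `c(xmin, xmax, ymin, ymax)` in metres.
#' @param cell_size Raster resolution in metres.
#' @param smoothness Correlation length (Gaussian kernel SD) in metres; must
#'   be at least `cell_size`.
#' @param seed Integer seed; the surface is deterministic given the seed.
#' @return A `landscape_raster`: list with `origin_x`, `origin_y`,
#'   `cell_size`, `n_rows`, `n_cols` and a `values` matrix (`n_rows` x
#'   `n_cols`, row 1 at the lowest y), all values in (0, 1].
#' @export
#' @examples
#' r <- generate_rsf_surface(study_extent(), cell_size = 2000,
#'                           smoothness = 6000, seed = 1)
#' range(r$values)
generate_rsf_surface <- function(extent, cell_size, smoothness, seed = 1L) {
  extent <- check_extent(extent)
  if (cell_size <= 0) stop("`cell_size` must be positive", call. = FALSE)
  if (smoothness < cell_size) {
    stop("`smoothness` must be at least `cell_size`", call. = FALSE)
  }
  n_cols <- as.integer(ceiling(extent_width(extent) / cell_size - 1e-9))
  n_rows <- as.integer(ceiling(extent_height(extent) / cell_size - 1e-9))
  set.seed(substream_seed(seed, "rsf"))
  noise <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  smooth <- fft_gaussian_smooth(noise, sigma_cells = smoothness / cell_size)
  values <- 0.05 + 0.95 * stats::pnorm(smooth)
  new_landscape_raster(extent[["xmin"]], extent[["ymin"]], cell_size, values)
}

new_landscape_raster <- function(origin_x, origin_y, cell_size, values) {
  structure(
    list(origin_x = origin_x, origin_y = origin_y, cell_size = cell_size,
         n_rows = nrow(values), n_cols = ncol(values), values = values),
    class = "landscape_raster"
  )
}

# Periodic convolution with a normalized 2-d Gaussian kernel via FFT.
fft_gaussian_smooth <- function(m, sigma_cells) {
  nr <- nrow(m); nc <- ncol(m)
  gauss <- function(n) {
    d <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    exp(-d^2 / (2 * sigma_cells^2))
  }
  k <- outer(gauss(nr), gauss(nc))
  k <- k / sum(k)
  Re(stats::fft(stats::fft(m) * stats::fft(k), inverse = TRUE)) / (nr * nc)
}

#' @export
print.landscape_raster <- function(x, ...) {
  cat(sprintf(
    "<landscape_raster: %d x %d cells of %g m, origin (%g, %g), values [%.3f, %.3f]>\n",
    x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y,
    min(x$values), max(x$values)
  ))
  invisible(x)
}

#' @method as_tibble landscape_raster
#' @export
as_tibble.landscape_raster <- function(x, ...) {
  tibble::tibble(
    row = rep(seq_len(x$n_rows), times = x$n_cols),
    col = rep(seq_len(x$n_cols), each = x$n_rows),
    x_m = x$origin_x + (rep(seq_len(x$n_cols), each = x$n_rows) - 0.5) * x$cell_size,
    y_m = x$origin_y + (rep(seq_len(x$n_rows), times = x$n_cols) - 0.5) * x$cell_size,
    value = as.vector(x$values)
  )
}

# Habitat weight at planar coordinates; coordinates beyond the raster clamp
# to the edge cell (rasters are padded in scenario runs so this is rare).
landscape_value <- function(raster, x, y) {
  col <- pmin(pmax(floor((x - raster$origin_x) / raster$cell_size) + 1, 1), raster$n_cols)
  row <- pmin(pmax(floor((y - raster$origin_y) / raster$cell_size) + 1, 1), raster$n_rows)
  raster$values[cbind(row, col)]
}

#' Generate synthetic linear landscape features
#'
#' Roads and pipelines are near-straight edge-to-edge transects; rivers are
#' meandering many-vertex polylines. Used as crossing targets for
#' path-characteristic statistics.
#'
#' @param extent Numeric `c(xmin, xmax, ymin, ymax)` in metres.
#' @param n_per_kind Named counts, e.g. `c(road = 5, pipeline = 5, river = 3)`;
#'   names must be drawn from road/pipeline/river.
#' @param seed Integer seed.
#' @return A tibble with columns `kind`, `feature_id`, `vertex`, `x_m`,
#'   `y_m`; one row per polyline vertex.
#' @export
generate_line_features <- function(extent,
                                   n_per_kind = c(road = 5, pipeline = 5, river = 3),
                                   seed = 1L) {
  extent <- check_extent(extent)
  kinds <- c("road", "pipeline", "river")
  if (is.null(names(n_per_kind)) || !all(names(n_per_kind) %in% kinds)) {
    stop("`n_per_kind` must be named with kinds road/pipeline/river", call. = FALSE)
  }
  stopifnot(all(n_per_kind >= 0))
  set.seed(substream_seed(seed, "features"))
  w <- extent_width(extent); h <- extent_height(extent)
  feats <- list()
  fid <- 0L
  for (kind in kinds) {
    n_k <- if (kind %in% names(n_per_kind)) n_per_kind[[kind]] else 0
    for (i in seq_len(n_k)) {
      fid <- fid + 1L
      horizontal <- stats::runif(1) < 0.5
      if (kind == "river") {
        # meandering lateral random walk across the extent
        n_v <- 60L
        s <- seq(0, 1, length.out = n_v)
        lat0 <- stats::runif(1, 0.1, 0.9)
        lat <- lat0 + cumsum(stats::rnorm(n_v, 0, 0.02))
        lat <- pmin(pmax(lat, 0), 1)
        if (horizontal) {
          xs <- extent[["xmin"]] + s * w; ys <- extent[["ymin"]] + lat * h
        } else {
          xs <- extent[["xmin"]] + lat * w; ys <- extent[["ymin"]] + s * h
        }
      } else {
        # near-straight: two endpoints on opposite edges, slight midpoint jog
        a <- stats::runif(1, 0.05, 0.95); b <- stats::runif(1, 0.05, 0.95)
        mid <- (a + b) / 2 + stats::rnorm(1, 0, 0.01)
        if (horizontal) {
          xs <- extent[["xmin"]] + c(0, 0.5, 1) * w
          ys <- extent[["ymin"]] + c(a, mid, b) * h
        } else {
          xs <- extent[["xmin"]] + c(a, mid, b) * w
          ys <- extent[["ymin"]] + c(0, 0.5, 1) * h
        }
      }
      feats[[fid]] <- tibble::tibble(
        kind = kind, feature_id = fid, vertex = seq_along(xs),
        x_m = xs, y_m = ys
      )
    }
  }
  if (length(feats) == 0) {
    return(tibble::tibble(kind = character(), feature_id = integer(),
                          vertex = integer(), x_m = double(), y_m = double()))
  }
  dplyr::bind_rows(feats)
}

#' Generate synthetic GPS telemetry with known movement parameters
#'
#' Simulates wolves on a featureless (flat-habitat) landscape by chaining
#' the two-state correlated random walk over `n_days`, emitting one fix per
#' nominal interval. Ground truth for parameter-recovery tests: the
#' generating `movement_params` are attached as attribute `"params"`.
#'
#' @param params A [movement_params] object.
#' @param n_wolves Number of wolves (independent series).
#' @param n_days Days of tracking (>= 2); each day contributes
#'   `24 / step_interval` fixes after the initial fix.
#' @param seed Integer seed.
#' @param month Month label attached to every fix (defaults to the params'
#'   month).
#' @return A tibble with columns `wolf_id`, `timestamp_h`, `x_m`, `y_m`,
#'   `month`; `nominal_interval` and `params` as attributes.
#' @export
generate_synthetic_telemetry <- function(params, n_wolves = 11, n_days = 90,
                                         seed = 1L, month = NULL) {
  stopifnot(inherits(params, "movement_params"), n_wolves >= 1, n_days >= 2)
  month <- month %||% params$month
  fixes_per_wolf <- as.integer(n_days * 24 / params$step_interval)
  set.seed(substream_seed(seed, "telemetry"))
  sim <- simulate_paths_batch(
    n = n_wolves,
    start = cbind(stats::runif(n_wolves, 0, 1e5), stats::runif(n_wolves, 0, 1e5)),
    territory = NULL, params = params, landscape = NULL,
    n_steps = fixes_per_wolf
  )
  out <- tidy_paths(sim)
  out <- tibble::tibble(
    wolf_id = sprintf("W%02d", out$path_id),
    timestamp_h = out$step * params$step_interval,
    x_m = out$x_m, y_m = out$y_m,
    month = month
  )
  attr(out, "nominal_interval") <- params$step_interval
  attr(out, "params") <- params
  out
}
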
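# Shared helpers: angle arithmetic, extents, seed substreams.

#' Study extent used throughout the simulations
#'
#' A 120 km x 120 km square (14,400 km2), the area covered by every survey
#' grid. Coordinates are planar metres with the origin at the lower-left
#' corner.
#'
#' @param width_km,height_km Side lengths in kilometres.
#' @return Named numeric vector `c(xmin, xmax, ymin, ymax)` in metres.
#' @export
#' @examples
#' study_extent()
study_extent <- function(width_km = 120, height_km = 120) {
  stopifnot(width_km > 0, height_km > 0)
  c(xmin = 0, xmax = width_km * 1000, ymin = 0, ymax = height_km * 1000)
}

extent_width <- function(extent) unname(extent[["xmax"]] - extent[["xmin"]])
extent_height <- function(extent) unname(extent[["ymax"]] - extent[["ymin"]])
extent_area_km2 <- function(extent) extent_width(extent) * extent_height(extent) / 1e6

check_extent <- function(extent) {
  if (!is.numeric(extent) || length(extent) != 4) {
    stop("`extent` must be a numeric vector c(xmin, xmax, ymin, ymax)", call. = FALSE)
  }
  extent <- stats::setNames(as.numeric(extent), c("xmin", "xmax", "ymin", "ymax"))
  if (extent_width(extent) <= 0 || extent_height(extent) <= 0) {
    stop("`extent` must have positive width and height", call. = FALSE)
  }
  extent
}

# Wrap angles (degrees) into (-180, 180].
wrap_deg <- function(a) a - 360 * ceiling((a - 180) / 360)

deg2rad <- function(a) a * pi / 180
rad2deg <- function(a) a * 180 / pi

# Bearing (degrees, counter-clockwise from +x) of displacement (dx, dy).
bearing_deg <- function(dx, dy) rad2deg(atan2(dy, dx))

# Deterministic 32-bit sub-seed derived from a master seed and labels, so
# that named random substreams (layout, library, survey, ...) are
# reproducible and mutually comparable under paired designs.
substream_seed <- function(seed, ...) {
  labels <- paste(c(...), collapse = "/")
  h <- 0
  for (code in utf8ToInt(labels)) h <- (h * 31 + code) %% 2147483647L
  as.integer((as.double(seed) * 48271 + h) %% 2147483647L)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
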
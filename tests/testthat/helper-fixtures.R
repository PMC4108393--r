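# Shared fixtures, built in code.

# A constant-value habitat raster over a padded box (metres).
flat_raster <- function(value = 1, xmin = -5e4, xmax = 17e4, cell = 5000) {
  n <- ceiling((xmax - xmin) / cell)
  packtrack:::new_landscape_raster(xmin, xmin, cell,
                                   matrix(value, n, n))
}

# Left half `hi`, right half `lo`, split at x = split.
split_raster <- function(hi = 1, lo = 0.05, split = 0,
                         xmin = -2e5, xmax = 2e5, cell = 5000) {
  n <- ceiling((xmax - xmin) / cell)
  vals <- matrix(lo, n, n)
  centres <- xmin + (seq_len(n) - 0.5) * cell
  vals[, centres < split] <- hi
  packtrack:::new_landscape_raster(xmin, xmin, cell, vals)
}

# A path tibble from bare coordinates.
make_path <- function(x, y, path_id = 1L, owner = "pack") {
  tibble::tibble(path_id = path_id, owner = owner, pack_id = NA_integer_,
                 draw = NA_integer_, step = seq_along(x) - 1L,
                 x_m = x, y_m = y,
                 state = if (length(x)) c(NA, rep("moving", length(x) - 1)) else character(0))
}

# A telemetry tibble from bare coordinates at the nominal 2-h interval.
make_fixes <- function(x, y, wolf_id = "W01", month = "December") {
  out <- tibble::tibble(wolf_id = wolf_id,
                        timestamp_h = 2 * (seq_along(x) - 1),
                        x_m = x, y_m = y, month = month)
  attr(out, "nominal_interval") <- 2
  out
}

# Fast movement parameters for tests that only need a valid object.
test_params <- function(...) {
  movement_params("December", step_mean = 2000, step_sd = 1000,
                  step_max = 8000, turn_sd = 90, ...)
}

# A small scenario configuration that keeps sweeps cheap.
small_config <- function(...) {
  scenario_config(densities = c(0, 1), grid_areas = c(36, 576),
                  n_replicates = 3, library_size = 10, seed = 42, ...)
}

# Dense-sampling oracle for segment-grid intersection: closed-cell
# membership of many points along the segment.
oracle_segment_cells <- function(grid, x0, y0, x1, y1, n = 4001) {
  t <- seq(0, 1, length.out = n)
  ids <- unlist(lapply(t, function(ti) {
    packtrack:::cells_of_point(grid, x0 + ti * (x1 - x0), y0 + ti * (y1 - y0))
  }))
  sort(unique(ids))
}
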
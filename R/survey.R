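# Survey grids and virtual aerial track surveys: square cells tiling the
# study extent, a 20% random cell sample, perfect detection, and occupancy
# as the proportion of surveyed cells intersected by a wolf path.

#' Build a square survey grid over the extent
#'
#' Row-major indexed square cells tiling the extent exactly (cell ids run
#' left to right, bottom row first). The reference design uses cell areas
#' 36, 144, 400 and 576 km2 over the 14,400 km2 extent (400, 100, 36 and 25
#' cells).
#'
#' @param extent Numeric `c(xmin, xmax, ymin, ymax)` in metres.
#' @param cell_area_km2 Cell area in km2; the cell side must divide both
#'   extent sides exactly.
#' @return A `survey_grid` list: `extent`, `cell_area_km2`, `cell_side_m`,
#'   `n_x`, `n_y`, `n_cells`.
#' @export
#' @examples
#' build_grid(study_extent(), 36)$n_cells # 400
build_grid <- function(extent = study_extent(), cell_area_km2) {
  extent <- check_extent(extent)
  stopifnot(cell_area_km2 > 0)
  side <- sqrt(cell_area_km2) * 1000
  n_x <- extent_width(extent) / side
  n_y <- extent_height(extent) / side
  if (abs(n_x - round(n_x)) > 1e-9 || abs(n_y - round(n_y)) > 1e-9) {
    stop(sprintf("cell side %.3f km does not divide the extent exactly",
                 side / 1000), call. = FALSE)
  }
  n_x <- as.integer(round(n_x)); n_y <- as.integer(round(n_y))
  structure(
    list(extent = extent, cell_area_km2 = cell_area_km2, cell_side_m = side,
         n_x = n_x, n_y = n_y, n_cells = n_x * n_y),
    class = "survey_grid"
  )
}

#' @export
print.survey_grid <- function(x, ...) {
  cat(sprintf("<survey_grid: %d cells of %g km2 (%g km side), %d x %d>\n",
              x$n_cells, x$cell_area_km2, x$cell_side_m / 1000, x$n_x, x$n_y))
  invisible(x)
}

# Cell ids containing a point, under closed-cell semantics: a point exactly
# on a shared gridline belongs to both adjacent cells. Returns an integer
# vector of 1, 2 or 4 ids; empty when outside the grid.
cells_of_point <- function(grid, x, y, eps = 1e-9) {
  side <- grid$cell_side_m
  gx <- (x - grid$extent[["xmin"]]) / side
  gy <- (y - grid$extent[["ymin"]]) / side
  cols <- unique(pmax(1L, pmin(grid$n_x, c(
    floor(gx - eps) + 1, floor(gx + eps) + 1
  ))))
  rows <- unique(pmax(1L, pmin(grid$n_y, c(
    floor(gy - eps) + 1, floor(gy + eps) + 1
  ))))
  if (gx < -eps || gx > grid$n_x + eps || gy < -eps || gy > grid$n_y + eps) {
    return(integer(0))
  }
  as.integer(outer(cols, (rows - 1) * grid$n_x, "+"))
}

# Exact cells traversed by one segment: cut the segment at every interior
# gridline crossing and classify each sub-segment by its midpoint (closed
# cells: midpoints lying on a gridline - e.g. a segment running along one -
# count both adjacent cells).
segment_cells <- function(grid, x0, y0, x1, y1) {
  side <- grid$cell_side_m
  ex <- grid$extent
  ts <- c(0, 1)
  if (x1 != x0) {
    lo <- ceiling((min(x0, x1) - ex[["xmin"]]) / side)
    hi <- floor((max(x0, x1) - ex[["xmin"]]) / side)
    if (lo <= hi) {
      lines_x <- ex[["xmin"]] + (lo:hi) * side
      ts <- c(ts, (lines_x - x0) / (x1 - x0))
    }
  }
  if (y1 != y0) {
    lo <- ceiling((min(y0, y1) - ex[["ymin"]]) / side)
    hi <- floor((max(y0, y1) - ex[["ymin"]]) / side)
    if (lo <= hi) {
      lines_y <- ex[["ymin"]] + (lo:hi) * side
      ts <- c(ts, (lines_y - y0) / (y1 - y0))
    }
  }
  ts <- sort(unique(pmin(pmax(ts, 0), 1)))
  # classify sub-segments by midpoint, and include the crossing points
  # themselves so a corner touch marks all closed cells sharing the corner
  tt <- c(ts, (ts[-1] + ts[-length(ts)]) / 2)
  px <- x0 + tt * (x1 - x0)
  py <- y0 + tt * (y1 - y0)
  unique(unlist(lapply(seq_along(px), function(i) {
    cells_of_point(grid, px[i], py[i])
  })))
}

#' Cells of a grid intersected by wolf paths
#'
#' A cell is occupied iff any path segment geometrically intersects the
#' closed cell square, computed exactly by cutting each segment at
#' gridline crossings (not by vertex membership). Segments running along a
#' shared cell boundary occupy both adjacent cells; path portions beyond
#' the extent occupy nothing.
#'
#' @param paths A path tibble (columns `path_id`, `step`, `x_m`, `y_m`), as
#'   from [simulate_path()] or [generate_path_library()].
#' @param grid A `survey_grid` from [build_grid()].
#' @return Sorted integer vector of occupied cell ids.
#' @export
cell_intersections <- function(paths, grid) {
  if (nrow(paths) == 0) return(integer(0))
  occ <- logical(grid$n_cells)
  split_paths <- split(paths[c("x_m", "y_m")], paths$path_id)
  side <- grid$cell_side_m
  for (p in split_paths) {
    x <- p$x_m; y <- p$y_m
    n <- length(x)
    if (n < 2) {
      occ[cells_of_point(grid, x, y)] <- TRUE
      next
    }
    for (i in seq_len(n - 1)) {
      # fast path: both endpoints strictly inside the same cell
      c0 <- floor((x[i] - grid$extent[["xmin"]]) / side)
      c1 <- floor((x[i + 1] - grid$extent[["xmin"]]) / side)
      r0 <- floor((y[i] - grid$extent[["ymin"]]) / side)
      r1 <- floor((y[i + 1] - grid$extent[["ymin"]]) / side)
      if (c0 == c1 && r0 == r1 && c0 >= 0 && c0 < grid$n_x &&
          r0 >= 0 && r0 < grid$n_y) {
        occ[cells_of_point(grid, x[i], y[i])] <- TRUE
        occ[cells_of_point(grid, x[i + 1], y[i + 1])] <- TRUE
      } else {
        occ[segment_cells(grid, x[i], y[i], x[i + 1], y[i + 1])] <- TRUE
      }
    }
  }
  which(occ)
}

#' Randomly sample survey cells
#'
#' `round(fraction x n_cells)` distinct cells, uniform without replacement
#' (round-half-even, so 20% of 36 cells is 7); a sample rounding to zero is
#' forced to one cell with a warning.
#'
#' @param grid A `survey_grid`.
#' @param fraction Fraction of cells to survey (0 < fraction <= 1).
#' @param seed Optional integer seed.
#' @return Integer vector of sampled cell ids.
#' @export
sample_cells <- function(grid, fraction = 0.2, seed = NULL) {
  stopifnot(fraction > 0, fraction <= 1)
  if (!is.null(seed)) set.seed(substream_seed(seed, "cells"))
  k <- round(fraction * grid$n_cells)
  if (k == 0) {
    warning("sample fraction rounds to 0 cells; surveying 1 cell")
    k <- 1
  }
  sample.int(grid$n_cells, k)
}

#' Occupancy rate of a survey
#'
#' The proportion of surveyed cells intersected by a wolf path.
#'
#' @param paths A path tibble.
#' @param grid A `survey_grid`.
#' @param sampled_ids Surveyed cell ids (non-empty).
#' @return Fraction in `[0, 1]`.
#' @export
occupancy_rate <- function(paths, grid, sampled_ids) {
  if (length(sampled_ids) == 0) stop("no surveyed cells", call. = FALSE)
  occupied <- cell_intersections(paths, grid)
  length(intersect(occupied, sampled_ids)) / length(sampled_ids)
}

#' Replicate a virtual survey
#'
#' Each replicate redraws both the surveyed cells and (when `paths` is a
#' generator function) the wolf paths, then computes occupancy; mean and SD
#' across replicates summarize the survey.
#'
#' @param paths Either a fixed path tibble or a function of the replicate
#'   index returning one (used to redraw each pack's realized track
#'   network per replicate).
#' @param grid A `survey_grid`.
#' @param fraction Surveyed fraction of cells.
#' @param n_replicates Number of replicate surveys (10 in the reference
#'   design).
#' @param seed Integer seed for the cell draws.
#' @param resample_cells Redraw the surveyed cells each replicate
#'   (default); `FALSE` fixes one cell draw across replicates.
#' @return A list with `mean`, `sd`, and `replicates` (tibble `replicate`,
#'   `n_sampled`, `n_occupied`, `occupancy`).
#' @export
replicate_survey <- function(paths, grid, fraction = 0.2, n_replicates = 10,
                             seed = 1L, resample_cells = TRUE) {
  stopifnot(n_replicates >= 1)
  fixed_cells <- if (!resample_cells) {
    sample_cells(grid, fraction, seed = substream_seed(seed, "survey", 0))
  }
  reps <- purrr::map_dfr(seq_len(n_replicates), function(k) {
    ids <- if (resample_cells) {
      sample_cells(grid, fraction, seed = substream_seed(seed, "survey", k))
    } else fixed_cells
    p <- if (is.function(paths)) paths(k) else paths
    occupied <- cell_intersections(p, grid)
    hit <- intersect(occupied, ids)
    tibble::tibble(replicate = k, n_sampled = length(ids),
                   n_occupied = length(hit),
                   occupancy = length(hit) / length(ids))
  })
  list(mean = mean(reps$occupancy), sd = stats::sd(reps$occupancy),
       replicates = reps)
}
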
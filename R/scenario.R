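# Scenario assembly and sensitivity sweeps: movement month x pack cohesion
# x lone wolves x grid size x pack density, summarized as occupancy-
# abundance curves.

month_movement_params <- function(month) {
  switch(tolower(substr(month, 1, 3)),
         dec = december_params(),
         feb = february_params(),
         stop(sprintf("no built-in movement parameters for month '%s'", month),
              call. = FALSE))
}

#' Configure an occupancy-abundance scenario
#'
#' Bundles every knob of a simulation sweep. Defaults are the reference
#' study conditions: December movements, cohesive packs, no loners, pack
#' densities 0.0-5.5 by 0.5, grids of 36/144/400/576 km2, a 20% cell
#' sample, 10 replicate surveys, 1,000-path libraries, 8% territory
#' overlap, loner fraction 0.13 of the total population, mean pack size
#' 7.8.
#'
#' @param month `"December"` or `"February"` (selects built-in movement
#'   parameters unless `params` is supplied).
#' @param hunting_units Independent hunting units per pack (1, 2 or 4).
#' @param loners Include lone wolves?
#' @param loner_fraction Loners as a fraction of the total wolf population.
#' @param mean_pack_size Wolves per pack, used to convert pack density to
#'   wolf numbers for the loner count.
#' @param densities Pack densities (packs per 1,000 km2) to sweep.
#' @param grid_areas Survey-cell areas in km2.
#' @param survey_fraction Fraction of cells surveyed per replicate.
#' @param n_replicates Replicate surveys per density.
#' @param library_size Simulated paths per territory and month.
#' @param overlap_target Territory neighbour-overlap fraction.
#' @param extent Study extent in metres.
#' @param params Optional [movement_params] overriding the month defaults.
#' @param rsf_cell_m,rsf_smoothness_m Resolution and correlation length of
#'   the synthetic habitat surface (metres).
#' @param n_candidates Candidate steps per moving step (habitat-bias
#'   strength).
#' @param cumulative Nest hunting-unit path draws (the 1-unit draw is a
#'   subset of the 2-unit draw, etc.), for paired monotonicity analyses.
#' @param seed Master seed; all layout/library/selection/survey substreams
#'   derive from it.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(month = "December", hunting_units = 1,
                            loners = FALSE, loner_fraction = 0.13,
                            mean_pack_size = 7.8,
                            densities = seq(0, 5.5, by = 0.5),
                            grid_areas = c(36, 144, 400, 576),
                            survey_fraction = 0.2, n_replicates = 10,
                            library_size = 1000, overlap_target = 0.08,
                            extent = study_extent(), params = NULL,
                            rsf_cell_m = 500, rsf_smoothness_m = 5000,
                            n_candidates = 20, cumulative = FALSE,
                            seed = 1L) {
  stopifnot(hunting_units %in% c(1, 2, 4),
            loner_fraction >= 0, loner_fraction < 1,
            all(densities >= 0), n_replicates >= 1, library_size >= 1)
  params <- params %||% month_movement_params(month)
  structure(
    list(month = month, hunting_units = hunting_units, loners = loners,
         loner_fraction = loner_fraction, mean_pack_size = mean_pack_size,
         densities = densities, grid_areas = grid_areas,
         survey_fraction = survey_fraction, n_replicates = n_replicates,
         library_size = library_size, overlap_target = overlap_target,
         extent = check_extent(extent), params = params,
         rsf_cell_m = rsf_cell_m, rsf_smoothness_m = rsf_smoothness_m,
         n_candidates = n_candidates, cumulative = cumulative,
         seed = as.integer(seed)),
    class = "scenario_config"
  )
}

# Habitat surface padded one maximum territory diameter beyond the extent,
# so edge-territory and loner movement always has defined habitat weights.
scenario_landscape <- function(config) {
  dens_pos <- config$densities[config$densities > 0]
  pad <- if (length(dens_pos) == 0) 10000 else {
    2 * sqrt(territory_area_for_density(min(dens_pos)) * 1e6 / pi)
  }
  ex <- config$extent
  padded <- c(xmin = ex[["xmin"]] - pad, xmax = ex[["xmax"]] + pad,
              ymin = ex[["ymin"]] - pad, ymax = ex[["ymax"]] + pad)
  generate_rsf_surface(padded, config$rsf_cell_m, config$rsf_smoothness_m,
                       seed = substream_seed(config$seed, "landscape"))
}

#' Number of lone wolves implied by a layout
#'
#' Loners are a fraction of the *total* population (pack wolves plus
#' loners): `round(f / (1 - f) x n_packs x mean_pack_size)`.
#'
#' @param layout A `territory_layout` (or its pack count as an integer).
#' @param mean_pack_size Wolves per pack.
#' @param loner_fraction Loner fraction of the total population.
#' @return Integer loner count.
#' @export
#' @examples
#' loner_count(14, 7.8, 0.13) # 16
loner_count <- function(layout, mean_pack_size = 7.8, loner_fraction = 0.13) {
  stopifnot(loner_fraction >= 0, loner_fraction < 1)
  n_packs <- if (is.numeric(layout)) layout else nrow(layout)
  round(loner_fraction / (1 - loner_fraction) * n_packs * mean_pack_size)
}

#' Assemble one replicate's wolf paths from a path library
#'
#' Draws `hunting_units` paths per territory without replacement from that
#' territory's library (sampling the same path twice would collapse two
#' hunting units into one) and appends any lone-wolf paths. In cumulative
#' mode the draw for fewer units is, under the same seed, a prefix of the
#' draw for more units, enabling paired cohesion contrasts.
#'
#' @param library A path library from [generate_path_library()].
#' @param hunting_units Paths per territory (1, 2 or 4).
#' @param loner_paths Optional tibble of lone-wolf paths to append.
#' @param seed Optional integer seed for the draw.
#' @param cumulative Unused flag kept for clarity: the prefix property
#'   holds whenever the same `seed` is used, which is what this function
#'   guarantees.
#' @return A path tibble with distinct `path_id`s.
#' @export
assemble_scenario <- function(library, hunting_units = 1, loner_paths = NULL,
                              seed = NULL, cumulative = FALSE) {
  stopifnot(hunting_units >= 1)
  n_paths <- attr(library, "n_paths") %||% max(library$draw, na.rm = TRUE)
  if (n_paths < hunting_units) {
    stop("library smaller than the number of hunting units", call. = FALSE)
  }
  packs <- unique(library$pack_id)
  chosen <- purrr::map_dfr(packs, function(pk) {
    # per-pack substream: under one seed, the k-unit draw for a pack is a
    # prefix of its (k+1)-unit draw, giving nested cohesion scenarios
    if (!is.null(seed)) set.seed(substream_seed(seed, "select", pk))
    tibble::tibble(pack_id = pk, draw = sample.int(n_paths, hunting_units))
  })
  out <- dplyr::inner_join(library, chosen, by = c("pack_id", "draw"))
  if (!is.null(loner_paths) && nrow(loner_paths) > 0) {
    loner_paths$path_id <- loner_paths$path_id + max(out$path_id, 0)
    out <- dplyr::bind_rows(out, loner_paths)
  }
  out
}

empty_paths <- function() {
  tibble::tibble(path_id = integer(), owner = character(),
                 pack_id = integer(), draw = integer(), step = integer(),
                 x_m = double(), y_m = double(), state = character())
}

# One density's replicate occupancies for every grid; shared machinery for
# run_curve and stabilization_check. Returns tibble (grid_km2, replicate,
# n_sampled, n_occupied, occupancy).
run_density <- function(config, density, grids, landscape,
                        n_replicates = config$n_replicates) {
  seed <- config$seed
  dlab <- sprintf("d%.0f", density * 1000)
  layout <- layout_territories(config$extent, density, config$overlap_target,
                               seed = substream_seed(seed, "layout", dlab))
  library <- if (nrow(layout) > 0) {
    generate_path_library(layout, config$params, landscape,
                          n_paths = config$library_size,
                          seed = substream_seed(seed, "library", dlab),
                          n_candidates = config$n_candidates)
  } else empty_paths()
  n_lon <- if (config$loners && nrow(layout) > 0) {
    loner_count(layout, config$mean_pack_size, config$loner_fraction)
  } else 0
  purrr::map_dfr(seq_len(n_replicates), function(k) {
    paths <- if (nrow(library) > 0) {
      assemble_scenario(library, config$hunting_units,
                        seed = substream_seed(seed, "assemble", config$month,
                                              dlab, k))
    } else empty_paths()
    if (n_lon > 0) {
      lp <- simulate_loner_paths(config$extent, config$params, n_lon,
                                 landscape,
                                 seed = substream_seed(seed, "loner",
                                                       config$month, dlab, k),
                                 n_candidates = config$n_candidates)
      lp$path_id <- lp$path_id + max(paths$path_id, 0)
      paths <- dplyr::bind_rows(paths, lp)
    }
    purrr::map_dfr(seq_along(grids), function(gi) {
      grid <- grids[[gi]]
      ids <- sample_cells(grid, config$survey_fraction,
                          seed = substream_seed(seed, "cells", dlab, k,
                                                grid$cell_area_km2))
      occupied <- if (nrow(paths) > 0) cell_intersections(paths, grid) else integer(0)
      hit <- length(intersect(occupied, ids))
      tibble::tibble(grid_km2 = grid$cell_area_km2, replicate = k,
                     n_sampled = length(ids), n_occupied = hit,
                     occupancy = hit / length(ids))
    })
  })
}

#' Run one occupancy-abundance curve
#'
#' For each (grid size, pack density): lay out territories, simulate the
#' path library, run `n_replicates` virtual surveys (each redrawing the
#' surveyed cells, the per-territory path selection and any loner paths)
#' and average occupancy. One path draw per replicate is surveyed by all
#' grids, and layout/survey substreams do not depend on the month or
#' cohesion settings, so paired configs differing only in those are
#' directly contrastable.
#'
#' @param config A [scenario_config()].
#' @param landscape Optional pre-built `landscape_raster` (rebuilt from the
#'   config when `NULL`).
#' @return An `occupancy_curve` tibble: `month`, `hunting_units`, `loners`,
#'   `grid_km2`, `density`, `mean_occupancy`, `sd_occupancy`, plus a
#'   `replicates` attribute with per-replicate results.
#' @export
run_curve <- function(config, landscape = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  landscape <- landscape %||% scenario_landscape(config)
  grids <- lapply(config$grid_areas, function(a) build_grid(config$extent, a))
  reps <- purrr::map_dfr(config$densities, function(d) {
    dplyr::mutate(run_density(config, d, grids, landscape), density = d)
  })
  curve <- reps |>
    dplyr::group_by(.data$grid_km2, .data$density) |>
    dplyr::summarise(mean_occupancy = mean(.data$occupancy),
                     sd_occupancy = stats::sd(.data$occupancy),
                     .groups = "drop") |>
    dplyr::mutate(month = config$month, hunting_units = config$hunting_units,
                  loners = config$loners, .before = 1)
  structure(curve, class = c("occupancy_curve", class(curve)),
            replicates = reps, config = config)
}

#' Run the full sensitivity experiment
#'
#' The cross of months (December, February) x pack cohesion (1, 2, 4
#' hunting units) x loners (off, on) x grid sizes x densities, sharing
#' layouts and surveyed-cell draws across scenarios so the movement-rate,
#' cohesion and loner contrasts are paired.
#'
#' @param base_config A [scenario_config()] supplying densities, grids,
#'   replicate counts and the master seed.
#' @param months,hunting_units,loners Scenario axes to cross.
#' @return A tibble of occupancy-curve rows for every scenario, with a
#'   `scenario` label column (`movement_rate` / `cohesion` / `loners`
#'   facets are recovered by filtering on the axis columns).
#' @export
run_full_experiment <- function(base_config = scenario_config(),
                                months = c("December", "February"),
                                hunting_units = c(1, 2, 4),
                                loners = c(FALSE, TRUE)) {
  landscape <- scenario_landscape(base_config)
  grid_expand <- tidyr::expand_grid(month = months, hu = hunting_units,
                                    lon = loners)
  purrr::map_dfr(seq_len(nrow(grid_expand)), function(i) {
    cfg <- base_config
    cfg$month <- grid_expand$month[i]
    cfg$params <- month_movement_params(cfg$month)
    cfg$hunting_units <- grid_expand$hu[i]
    cfg$loners <- grid_expand$lon[i]
    run_curve(cfg, landscape = landscape)
  })
}

#' Stabilization of the mean occupancy over replicate surveys
#'
#' Running mean of occupancy over k = 1..`max_replicates` replicates for
#' one (density, grid) cell, and the smallest k at which the running mean
#' is within `tol` of the final mean.
#'
#' @param config A [scenario_config()].
#' @param density Pack density (packs per 1,000 km2).
#' @param grid_area_km2 Survey-cell area.
#' @param max_replicates Replicates to run (>= 2).
#' @param tol Stabilization tolerance on the running mean.
#' @return A tibble (`k`, `occupancy`, `running_mean`) with attribute
#'   `k_stable`.
#' @export
stabilization_check <- function(config, density, grid_area_km2,
                                max_replicates = 10, tol = 0.02) {
  stopifnot(max_replicates >= 2)
  landscape <- scenario_landscape(config)
  grid <- build_grid(config$extent, grid_area_km2)
  reps <- run_density(config, density, list(grid), landscape,
                      n_replicates = max_replicates)
  out <- tibble::tibble(
    k = reps$replicate,
    occupancy = reps$occupancy,
    running_mean = cumsum(reps$occupancy) / seq_along(reps$occupancy)
  )
  final <- out$running_mean[nrow(out)]
  k_stable <- min(out$k[abs(out$running_mean - final) < tol])
  attr(out, "k_stable") <- k_stable
  out
}
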
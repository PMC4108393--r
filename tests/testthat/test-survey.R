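test_that("grids tile the 14,400 km2 extent with the documented cell counts", {
  expect_identical(build_grid(cell_area_km2 = 36)$n_cells, 400L)
  expect_identical(build_grid(cell_area_km2 = 144)$n_cells, 100L)
  expect_identical(build_grid(cell_area_km2 = 400)$n_cells, 36L)
  expect_identical(build_grid(cell_area_km2 = 576)$n_cells, 25L)
  expect_identical(build_grid(cell_area_km2 = 14400)$n_cells, 1L)
  expect_error(build_grid(cell_area_km2 = 50), "divide")
})

test_that("cell sampling draws the rounded fraction without replacement", {
  g36 <- build_grid(cell_area_km2 = 36)
  ids <- sample_cells(g36, 0.2, seed = 1)
  expect_identical(length(ids), 80L)
  expect_identical(anyDuplicated(ids), 0L)
  expect_identical(length(sample_cells(build_grid(cell_area_km2 = 576), 0.2)), 5L)
  # 20% of 36 cells rounds half-even to 7
  expect_identical(length(sample_cells(build_grid(cell_area_km2 = 400), 0.2)), 7L)
  expect_identical(sort(sample_cells(g36, 1)), 1:400)
  g_one <- build_grid(cell_area_km2 = 14400)
  expect_warning(ids1 <- sample_cells(g_one, 0.2), "1 cell")
  expect_identical(ids1, 1L)
})

test_that("cell intersection is geometric, not vertex membership", {
  g <- build_grid(cell_area_km2 = 36)
  expect_identical(cell_intersections(make_path(numeric(0), numeric(0)), g),
                   integer(0))
  # vertex-only path inside cell (col 2, row 2)
  pt <- tibble::tibble(path_id = 1L, step = 0L, x_m = 7000, y_m = 7000)
  expect_identical(cell_intersections(pt, g), 22L)
  # a segment with endpoints two cells apart occupies the cell between them
  p <- make_path(c(1000, 17000), c(3000, 3000))
  expect_identical(cell_intersections(p, g), c(1L, 2L, 3L))
})

test_that("segment-grid cells match a dense-sampling oracle", {
  g <- build_grid(cell_area_km2 = 36)
  cases <- list(
    c(0, 0, 12000, 12000),          # corner-to-corner through a lattice node
    c(500, 500, 35500, 20500),      # generic diagonal
    c(2000, 6000, 40000, 6000),     # along a shared gridline
    c(-5000, 7000, 9000, 7000),     # entering from outside the extent
    c(3000, 3000, 3600, 4200)       # contained in one cell
  )
  for (cs in cases) {
    got <- sort(packtrack:::segment_cells(g, cs[1], cs[2], cs[3], cs[4]))
    want <- oracle_segment_cells(g, cs[1], cs[2], cs[3], cs[4])
    expect_identical(got, want)
  }
})

test_that("occupancy is the occupied fraction of surveyed cells", {
  g <- build_grid(cell_area_km2 = 36)
  p <- make_path(c(1000, 17000), c(3000, 3000)) # occupies cells 1:3
  expect_equal(occupancy_rate(p, g, c(1, 2, 3, 50, 60)), 0.6)
  expect_equal(occupancy_rate(p, g, 50:59), 0)
  expect_equal(occupancy_rate(p, g, 1:3), 1)
  expect_error(occupancy_rate(p, g, integer(0)), "no surveyed")
})

test_that("occupancy is always within [0, 1] and paths only add cells", {
  g <- build_grid(cell_area_km2 = 144)
  set.seed(21)
  paths <- purrr::map_dfr(1:10, function(i) {
    make_path(cumsum(c(runif(1, 0, 12e4), rnorm(24, 0, 3000))),
              cumsum(c(runif(1, 0, 12e4), rnorm(24, 0, 3000))), path_id = i)
  })
  occ_all <- cell_intersections(paths, g)
  for (k in 1:9) {
    occ_k <- cell_intersections(dplyr::filter(paths, path_id <= k), g)
    occ_k1 <- cell_intersections(dplyr::filter(paths, path_id <= k + 1), g)
    expect_true(all(occ_k %in% occ_k1))
  }
  ids <- sample_cells(g, 0.2, seed = 3)
  o <- occupancy_rate(paths, g, ids)
  expect_gte(o, 0)
  expect_lte(o, 1)
})

test_that("census occupancy is non-decreasing across nested grids", {
  grids <- lapply(c(36, 144, 576), function(a) build_grid(cell_area_km2 = a))
  set.seed(22)
  for (rep in 1:5) {
    paths <- purrr::map_dfr(1:6, function(i) {
      make_path(cumsum(c(runif(1, 0, 12e4), rnorm(10, 0, 4000))),
                cumsum(c(runif(1, 0, 12e4), rnorm(10, 0, 4000))), path_id = i)
    })
    occ <- vapply(grids, function(g) {
      length(cell_intersections(paths, g)) / g$n_cells
    }, numeric(1))
    expect_true(all(diff(occ) >= -1e-12))
  }
})

test_that("a 20% sample estimates census occupancy without bias", {
  g <- build_grid(cell_area_km2 = 36)
  set.seed(23)
  paths <- purrr::map_dfr(1:8, function(i) {
    make_path(cumsum(c(runif(1, 0, 12e4), rnorm(24, 0, 3000))),
              cumsum(c(runif(1, 0, 12e4), rnorm(24, 0, 3000))), path_id = i)
  })
  census <- length(cell_intersections(paths, g)) / g$n_cells
  means <- vapply(1:400, function(k) {
    occupancy_rate(paths, g, sample_cells(g, 0.2, seed = k))
  }, numeric(1))
  expect_lt(abs(mean(means) - census), 0.015)
})

test_that("replicate surveys summarize occupancy with redrawn cells", {
  g <- build_grid(cell_area_km2 = 576)
  p <- make_path(c(10000, 90000), c(50000, 60000))
  # full census of fixed paths is deterministic
  out <- replicate_survey(p, g, fraction = 1, n_replicates = 5, seed = 2)
  expect_equal(out$sd, 0)
  expect_identical(nrow(out$replicates), 5L)
  # a path generator is invoked per replicate
  calls <- integer(0)
  gen <- function(k) { calls <<- c(calls, k); p }
  out2 <- replicate_survey(gen, g, fraction = 0.2, n_replicates = 4, seed = 2)
  expect_identical(calls, 1:4)
  expect_true(all(out2$replicates$n_sampled == 5))
})
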
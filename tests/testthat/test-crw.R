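test_that("degenerate step draws collapse to their parameters", {
  # p_move = 1, step_sd = 0: every length is the mean
  p <- movement_params("t", step_mean = 2500, step_sd = 0, p_move = 1)
  set.seed(1)
  d <- draw_step(NA, p, n = 50)
  expect_true(all(d$state == "moving"))
  expect_true(all(d$length_m == 2500))
  # turn_sd -> 0, turn_mean = 0: heading preserved
  p2 <- movement_params("t", 2500, 1000, turn_mean = 0, turn_sd = 1e-9,
                        p_move = 1)
  set.seed(2)
  d2 <- draw_step(37, p2, n = 50)
  expect_equal(d2$bearing_deg, rep(37, 50), tolerance = 1e-6)
})

test_that("December moving draws reproduce the empirical mean step", {
  set.seed(10)
  d <- draw_step(NA, december_params(), n = 2e5)
  mv <- d$length_m[d$state == "moving"]
  expect_gt(length(mv), 1e5)
  expect_lt(abs(mean(mv) - 3013) / 3013, 0.02)
  expect_true(all(mv > 150 & mv <= 12283))
  nm <- d$length_m[d$state == "not_moving"]
  expect_true(all(nm < 150))
})

test_that("flat-landscape candidate selection reduces to the marginal draw", {
  p <- december_params()
  set.seed(3)
  sim <- packtrack:::simulate_paths_batch(
    n = 600, start = cbind(rep(0, 600), rep(0, 600)), territory = NULL,
    params = p, landscape = flat_raster(), n_steps = 24
  )
  lens <- sqrt(diff(t(sim$x))^2 + diff(t(sim$y))^2) # n_steps x n
  mv <- lens[t(sim$state)]
  trunc_cdf <- function(q) {
    lo <- plnorm(150, p$meanlog, p$sdlog)
    hi <- plnorm(12283, p$meanlog, p$sdlog)
    (plnorm(q, p$meanlog, p$sdlog) - lo) / (hi - lo)
  }
  ks <- suppressWarnings(stats::ks.test(mv, trunc_cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("habitat bias pulls vertices into the high-quality half", {
  land <- split_raster(hi = 1, lo = 0.05, split = 0)
  set.seed(4)
  sim <- packtrack:::simulate_paths_batch(
    n = 300, start = cbind(rep(0, 300), rep(0, 300)), territory = NULL,
    params = december_params(), landscape = land, n_steps = 24
  )
  frac_high <- mean(sim$x[, -1] < 0)
  expect_gt(frac_high, 0.55)
})

test_that("pack paths are confined to their territory circle", {
  r <- sqrt(182e6 / pi) # 182 km2
  terr <- list(cx = 0, cy = 0, radius = r)
  for (s in 1:5) {
    path <- simulate_path(terr, december_params(), seed = s)
    expect_identical(nrow(path), 25L)
    expect_true(all(sqrt(path$x_m^2 + path$y_m^2) <= r + 1e-6))
  }
})

test_that("path libraries have the configured size and are reproducible", {
  L <- layout_territories(density = 1, seed = 1)
  lib <- generate_path_library(L, test_params(), n_paths = 10, seed = 5)
  expect_identical(length(unique(lib$path_id)), nrow(L) * 10L)
  expect_identical(nrow(lib), nrow(L) * 10L * 25L)
  expect_setequal(unique(lib$draw), 1:10)
  lib1 <- generate_path_library(L, test_params(), n_paths = 1, seed = 5)
  expect_identical(length(unique(lib1$path_id)), nrow(L))
  expect_identical(lib, generate_path_library(L, test_params(), n_paths = 10, seed = 5))
  # every vertex inside its owning territory
  joined <- dplyr::left_join(lib, tibble::as_tibble(L), by = "pack_id")
  expect_true(all(sqrt((joined$x_m - joined$cx)^2 + (joined$y_m - joined$cy)^2)
                  <= joined$radius_m + 1e-6))
})

test_that("with one candidate the habitat bias vanishes", {
  p <- december_params()
  land <- split_raster()
  set.seed(6); sim_land <- packtrack:::simulate_paths_batch(
    50, cbind(rep(0, 50), rep(0, 50)), NULL, p, land, 24, n_candidates = 1)
  set.seed(6); sim_null <- packtrack:::simulate_paths_batch(
    50, cbind(rep(0, 50), rep(0, 50)), NULL, p, NULL, 24, n_candidates = 1)
  expect_identical(sim_land$x, sim_null$x)
  expect_identical(sim_land$y, sim_null$y)
})

test_that("loner paths are unconstrained, optional and deterministic", {
  expect_identical(nrow(simulate_loner_paths(study_extent(), n_loners = 0)), 0L)
  a <- simulate_loner_paths(study_extent(), test_params(), n_loners = 5, seed = 7)
  b <- simulate_loner_paths(study_extent(), test_params(), n_loners = 5, seed = 7)
  expect_identical(a, b)
  expect_identical(length(unique(a$path_id)), 5L)
  expect_true(all(a$owner == "loner"))
})

test_that("confinement changes displacement but not expected path length", {
  p <- december_params()
  r <- sqrt(1000e6 / pi)
  L <- tibble::tibble(pack_id = 1L, cx = 0, cy = 0, radius_m = r,
                      area_km2 = 1000)
  lib <- generate_path_library(L, p, n_paths = 400, seed = 8)
  lon <- simulate_loner_paths(study_extent(), p, n_loners = 400, seed = 8)
  stat <- function(df) {
    df |>
      dplyr::group_by(path_id) |>
      dplyr::summarise(
        len = sum(sqrt(diff(x_m)^2 + diff(y_m)^2)),
        disp = sqrt((x_m[dplyr::n()] - x_m[1])^2 + (y_m[dplyr::n()] - y_m[1])^2)
      )
  }
  sp <- stat(lib); sl <- stat(lon)
  expect_gte(mean(sl$disp), mean(sp$disp))
  # confinement trims boundary-bound candidates, so pack paths run a few
  # percent shorter than unconstrained ones under the same parameters
  expect_lt(abs(mean(sl$len) - mean(sp$len)) / mean(sl$len), 0.10)
  # unconstrained 2-day length matches the step-mixture expectation within 5%
  e_len <- 24 * (p$p_move * p$step_mean + (1 - p$p_move) * 75)
  expect_lt(abs(mean(sl$len) - e_len) / e_len, 0.05)
})
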
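test_that("step decomposition follows the straight-line/turn definitions", {
  # 3-4-5 displacement
  s <- compute_steps(make_fixes(c(0, 3000), c(0, 4000)))
  expect_identical(nrow(s), 1L)
  expect_equal(s$length_m, 5000)
  expect_true(is.na(s$turn_deg))
  # collinear fixes turn 0
  s <- compute_steps(make_fixes(c(0, 1000, 2000), c(0, 0, 0)))
  expect_equal(s$turn_deg, c(NA, 0))
  # left turn is counter-clockwise positive
  s <- compute_steps(make_fixes(c(0, 1000, 1000), c(0, 0, 1000)))
  expect_equal(s$turn_deg[2], 90)
  # right turn negative
  s <- compute_steps(make_fixes(c(0, 1000, 1000), c(0, 0, -1000)))
  expect_equal(s$turn_deg[2], -90)
})

test_that("steps spanning flagged gaps are excluded", {
  fixes <- make_fixes(c(0, 1000, 2000, 3000), c(0, 0, 0, 0))
  fixes$timestamp_h <- c(0, 2, 7, 9) # 2 -> 7 is a >10% gap
  s <- compute_steps(fixes)
  expect_identical(nrow(s), 2L)
  # turn after the gap is undefined
  expect_true(all(is.na(s$turn_deg)))
})

test_that("fewer than two fixes gives an empty step series", {
  s <- compute_steps(make_fixes(0, 0))
  expect_identical(nrow(s), 0L)
})

test_that("fitted parameters recover degenerate and counted quantities", {
  # identical 2,000 m steps, all moving
  fixes <- make_fixes(seq(0, 80000, by = 2000), rep(0, 41))
  s <- compute_steps(fixes)
  p <- fit_movement_params(s)
  expect_equal(p$step_mean, 2000)
  expect_equal(p$step_sd, 0)
  expect_equal(p$p_move, 1)
  # 40 moving / 60 not-moving -> p_move 0.40
  s2 <- tibble::tibble(
    wolf_id = "W01", t0_h = 0, length_m = c(rep(1000, 40), rep(50, 60)),
    bearing_deg = 0, turn_deg = NA_real_,
    state = c(rep("moving", 40), rep("not_moving", 60)), month = "December"
  )
  p2 <- fit_movement_params(s2)
  expect_equal(p2$p_move, 0.4)
  expect_equal(p2$step_mean, 1000)
})

test_that("too few moving steps is refused with a diagnostic", {
  s <- compute_steps(make_fixes(c(0, 3000, 6000), c(0, 0, 0)))
  expect_error(fit_movement_params(s), "moving steps")
})

test_that("simulated steps round-trip exactly through the decomposition", {
  path <- simulate_path(params = test_params(), seed = 8)
  fixes <- make_fixes(path$x_m, path$y_m)
  s <- compute_steps(fixes)
  seg <- sqrt(diff(path$x_m)^2 + diff(path$y_m)^2)
  expect_equal(s$length_m, seg)
  expect_identical(s$state, path$state[-1])
})

test_that("method-of-moments step statistics are recovered from telemetry", {
  p <- december_params()
  tel <- generate_synthetic_telemetry(p, n_wolves = 10, n_days = 84, seed = 13)
  s <- compute_steps(tel)
  fit <- fit_movement_params(s, month = "December")
  n_mv <- attr(fit, "n_moving")
  expect_gt(n_mv, 1000)
  # within 3 standard errors of the generating truth
  expect_lt(abs(fit$step_mean - p$step_mean), 3 * p$step_sd / sqrt(n_mv))
  expect_lt(abs(fit$p_move - p$p_move),
            3 * sqrt(p$p_move * (1 - p$p_move) / nrow(s)))
  # circular SD of turning angles close to the generating wrapped-normal sigma
  expect_lt(abs(fit$turn_sd - p$turn_sd), 5)
})

test_that("monthly step comparisons behave like Welch t-tests", {
  # identical samples -> t = 0, p = 1
  lens <- c(200, 500, 900, 1600, 2500, 4000)
  s <- tibble::tibble(
    wolf_id = "W01", t0_h = 0, length_m = rep(lens, 2), bearing_deg = 0,
    turn_deg = NA_real_, state = "moving",
    month = rep(c("December", "February"), each = length(lens))
  )
  out <- compare_monthly_steps(s)
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)
  # separated means detected; label swap negates t, keeps p
  set.seed(31)
  a <- stats::rnorm(400, 3000, 800); b <- stats::rnorm(400, 2400, 800)
  s2 <- tibble::tibble(
    wolf_id = "W01", t0_h = 0, length_m = c(a, b), bearing_deg = 0,
    turn_deg = NA_real_, state = "moving",
    month = rep(c("April", "March"), c(400, 400))
  )
  out2 <- compare_monthly_steps(s2)
  expect_lt(out2$p_value, 0.05)
  s3 <- s2
  s3$month <- rep(c("March", "April"), c(400, 400))
  out3 <- compare_monthly_steps(s3)
  expect_equal(out3$statistic, -out2$statistic)
  expect_equal(out3$p_value, out2$p_value)
  # single month -> empty result
  expect_identical(nrow(compare_monthly_steps(dplyr::filter(s2, month == "April"))), 0L)
})

test_that("MCP areas follow convex-hull geometry", {
  sq <- tibble::tibble(x_m = c(0, 10000, 10000, 0), y_m = c(0, 0, 10000, 10000))
  expect_equal(compute_mcp_area(sq), 100)
  # interior points do not change the hull
  sq2 <- dplyr::bind_rows(sq, tibble::tibble(x_m = 5000, y_m = 5000))
  expect_equal(compute_mcp_area(sq2), 100)
  # points in a 10 km disc are bounded by the disc area
  set.seed(5)
  r <- 10000 * sqrt(stats::runif(100)); a <- stats::runif(100, 0, 2 * pi)
  disc <- tibble::tibble(x_m = r * cos(a), y_m = r * sin(a))
  expect_lte(compute_mcp_area(disc), pi * 100)
  # collinear fixes warn and return 0
  lin <- tibble::tibble(x_m = c(0, 1000, 2000), y_m = c(0, 1000, 2000))
  expect_warning(area <- compute_mcp_area(lin), "collinear")
  expect_equal(area, 0)
})

test_that("movement-territory correlation is a Spearman test", {
  out <- movement_territory_correlation(1:8, (1:8)^2)
  expect_equal(out$rho, 1)
  out2 <- movement_territory_correlation(1:8, rev((1:8)^2))
  expect_equal(out2$rho, -1)
  # independent pairs at n = 11 are rarely significant
  set.seed(77)
  hits <- vapply(1:200, function(i) {
    movement_territory_correlation(stats::rnorm(11), stats::rnorm(11))$p_value > 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  expect_error(movement_territory_correlation(1:3, 1:3), ">= 4")
})
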
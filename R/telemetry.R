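# Telemetry step decomposition (Turchin definitions), month-specific
# movement-parameter fits, and home-range/movement summary statistics.

#' Decompose a GPS fix series into steps
#'
#' Step length is the straight-line distance between consecutive fixes;
#' turning angle is the change in bearing between consecutive steps,
#' counter-clockwise positive, wrapped to (-180, 180], undefined for the
#' first step of a series (and after any flagged gap). A step is "moving"
#' iff its length strictly exceeds the 150 m threshold. Fix intervals
#' deviating more than 10% from the nominal interval are flagged as gaps;
#' steps spanning a gap are excluded.
#'
#' @param series A tibble with columns `wolf_id`, `timestamp_h`, `x_m`,
#'   `y_m` and optionally `month` (as from
#'   [generate_synthetic_telemetry()]).
#' @param nominal_interval Nominal fix interval in hours.
#' @param move_threshold Moving/not-moving threshold in metres.
#' @return A tibble with one row per retained step: `wolf_id`, `t0_h`,
#'   `length_m`, `bearing_deg`, `turn_deg` (`NA` where undefined), `state`,
#'   `month`.
#' @export
compute_steps <- function(series, nominal_interval = NULL,
                          move_threshold = 150) {
  nominal_interval <- nominal_interval %||%
    attr(series, "nominal_interval") %||% 2
  if (!all(c("wolf_id", "timestamp_h", "x_m", "y_m") %in% names(series))) {
    stop("`series` needs columns wolf_id, timestamp_h, x_m, y_m", call. = FALSE)
  }
  if (!"month" %in% names(series)) series$month <- NA_character_
  series |>
    dplyr::group_by(.data$wolf_id) |>
    dplyr::arrange(.data$timestamp_h, .by_group = TRUE) |>
    dplyr::group_modify(function(df, key) steps_one(df, nominal_interval, move_threshold)) |>
    dplyr::ungroup()
}

steps_one <- function(df, nominal_interval, move_threshold) {
  n <- nrow(df)
  empty <- tibble::tibble(t0_h = double(), length_m = double(),
                          bearing_deg = double(), turn_deg = double(),
                          state = character(), month = character())
  if (n < 2) return(empty)
  if (any(diff(df$timestamp_h) <= 0)) {
    stop("timestamps must be strictly increasing within a wolf", call. = FALSE)
  }
  dt <- diff(df$timestamp_h)
  gap <- abs(dt - nominal_interval) > 0.1 * nominal_interval
  dx <- diff(df$x_m); dy <- diff(df$y_m)
  len <- sqrt(dx^2 + dy^2)
  brg <- bearing_deg(dx, dy)
  turn <- c(NA_real_, wrap_deg(diff(brg)))
  # a turn is defined only when both this step and the previous are gap-free
  turn[c(FALSE, gap[-length(gap)])] <- NA_real_
  keep <- !gap
  tibble::tibble(
    t0_h = df$timestamp_h[-n][keep],
    length_m = len[keep],
    bearing_deg = brg[keep],
    turn_deg = turn[keep],
    state = ifelse(len[keep] > move_threshold, "moving", "not_moving"),
    month = df$month[-n][keep]
  )
}

circular_mean_deg <- function(a) {
  rad <- deg2rad(a)
  wrap_deg(rad2deg(atan2(mean(sin(rad)), mean(cos(rad)))))
}

# Circular SD sqrt(-2 log Rbar) in degrees; consistent estimator of the
# wrapped-normal sigma used by the simulator.
circular_sd_deg <- function(a) {
  rad <- deg2rad(a)
  rbar <- sqrt(mean(sin(rad))^2 + mean(cos(rad))^2)
  rad2deg(sqrt(-2 * log(rbar)))
}

#' Fit month-specific movement parameters from a step series
#'
#' Natural-scale sample mean/SD of moving-step lengths (the log-normal is
#' parameterized from these by method of moments, see [movement_params()]),
#' the moving fraction `p_move` over all steps, circular mean and circular
#' SD of turning angles, and the observed moving-step range as truncation
#' bounds. Turning angles are taken from consecutive pairs of moving steps
#' only: a bearing recorded while stationary is jitter, not travel
#' direction, and would dilute the directional-persistence estimate.
#'
#' @param steps A step tibble from [compute_steps()].
#' @param month Month label to fit (matched against the `month` column);
#'   `NULL` pools all steps.
#' @param min_moving Minimum number of moving steps required.
#' @return A [movement_params] object with attributes `n_steps`,
#'   `n_moving`.
#' @export
fit_movement_params <- function(steps, month = NULL, min_moving = 30) {
  if (!is.null(month)) steps <- dplyr::filter(steps, .data$month == !!month)
  if (!"wolf_id" %in% names(steps)) steps$wolf_id <- "all"
  steps <- steps |>
    dplyr::group_by(.data$wolf_id) |>
    dplyr::mutate(.prev_moving = dplyr::lag(.data$state) == "moving") |>
    dplyr::ungroup()
  mv <- dplyr::filter(steps, .data$state == "moving")
  if (nrow(mv) < min_moving) {
    stop(sprintf("only %d moving steps (%d required) %s", nrow(mv), min_moving,
                 if (is.null(month)) "" else paste0("in ", month)),
         call. = FALSE)
  }
  mv2 <- dplyr::filter(mv, .data$.prev_moving %in% TRUE)
  turns <- mv2$turn_deg[!is.na(mv2$turn_deg)]
  p <- movement_params(
    month = month %||% (unique(steps$month)[1] %||% NA_character_),
    step_mean = mean(mv$length_m),
    step_sd = stats::sd(mv$length_m),
    step_min = min(mv$length_m),
    step_max = max(mv$length_m),
    turn_mean = if (length(turns)) circular_mean_deg(turns) else 0,
    turn_sd = if (length(turns) > 1) circular_sd_deg(turns) else 1e-6,
    p_move = mean(steps$state == "moving")
  )
  attr(p, "n_steps") <- nrow(steps)
  attr(p, "n_moving") <- nrow(mv)
  p
}

#' Compare moving-step lengths between months
#'
#' Welch two-sample t-test on moving-step lengths for every pair of months
#' present in the series.
#'
#' @param steps A step tibble from [compute_steps()] with a `month` column.
#' @return A tibble with one row per month pair: `month_a`, `month_b`,
#'   `n_a`, `n_b`, `mean_a`, `mean_b`, `statistic` (t, sign of
#'   `mean_a - mean_b`), `p_value`. Zero rows when fewer than two months
#'   are present.
#' @export
compare_monthly_steps <- function(steps) {
  mv <- dplyr::filter(steps, .data$state == "moving", !is.na(.data$month))
  months <- sort(unique(mv$month))
  if (length(months) < 2) {
    return(tibble::tibble(month_a = character(), month_b = character(),
                          n_a = integer(), n_b = integer(),
                          mean_a = double(), mean_b = double(),
                          statistic = double(), p_value = double()))
  }
  pairs <- utils::combn(months, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- mv$length_m[mv$month == pairs[1, k]]
    b <- mv$length_m[mv$month == pairs[2, k]]
    tt <- welch_t(a, b)
    tibble::tibble(
      month_a = pairs[1, k], month_b = pairs[2, k],
      n_a = length(a), n_b = length(b),
      mean_a = mean(a), mean_b = mean(b),
      statistic = tt$statistic, p_value = tt$p_value
    )
  })
}

welch_t <- function(a, b) {
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    # degenerate: identical constants compare equal
    return(list(statistic = 0, p_value = 1))
  }
  tt <- stats::t.test(a, b)
  list(statistic = unname(tt$statistic), p_value = tt$p.value)
}

#' Minimum convex polygon (100% MCP) area of a fix series
#'
#' Convex-hull area of all fixes, the standard winter home-range estimate.
#'
#' @param series A tibble with `x_m`, `y_m` (one wolf).
#' @return Area in km2 (0, with a warning, for collinear fixes).
#' @export
compute_mcp_area <- function(series) {
  pts <- unique(cbind(series$x_m, series$y_m))
  if (nrow(pts) < 3) stop("need >= 3 distinct fixes for an MCP", call. = FALSE)
  hull <- grDevices::chull(pts)
  hx <- pts[hull, 1]; hy <- pts[hull, 2]
  area_m2 <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  if (area_m2 == 0) warning("collinear fixes: MCP area is 0")
  area_m2 / 1e6
}

#' Correlation between movement rate and territory size
#'
#' Spearman rank correlation between per-wolf mean step length and MCP
#' area (ties handled by average ranks).
#'
#' @param mean_step_by_wolf,mcp_by_wolf Paired numeric vectors.
#' @return A tibble with `rho`, `p_value`, `n`.
#' @export
movement_territory_correlation <- function(mean_step_by_wolf, mcp_by_wolf) {
  stopifnot(length(mean_step_by_wolf) == length(mcp_by_wolf))
  if (length(mean_step_by_wolf) < 4) {
    stop("need >= 4 paired values", call. = FALSE)
  }
  ct <- suppressWarnings(
    stats::cor.test(mean_step_by_wolf, mcp_by_wolf, method = "spearman",
                    exact = FALSE)
  )
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value,
                 n = length(mean_step_by_wolf))
}
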
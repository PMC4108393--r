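# Movement parameter sets: month-specific step-length / turning-angle
# distributions, moving-state probability and the 150 m movement threshold.

#' Construct a wolf movement parameter set
#'
#' Bundles the month-specific two-hour movement statistics that drive the
#' correlated random walk: natural-scale mean and SD of moving-step lengths,
#' the observed step-length range used as truncation bounds, circular mean
#' and SD of turning angles, and the marginal probability that a two-hour
#' step is in the "moving" state. Moving steps are drawn from a log-normal
#' distribution truncated to `[move_threshold, step_max]`; the log-scale
#' parameters are solved numerically so the *truncated* distribution has
#' mean `step_mean` and SD `step_sd` (plain method-of-moments values are the
#' starting point of the solve).
#'
#' @param month Label, e.g. `"December"`.
#' @param step_mean,step_sd Natural-scale mean and SD of moving-step lengths, metres.
#' @param step_min,step_max Observed moving-step range, metres. `step_max` is
#'   the upper truncation bound of simulated moving steps.
#' @param turn_mean,turn_sd Circular mean and SD of turning angles, degrees.
#' @param p_move Probability that a two-hour step is a moving step.
#' @param step_interval Fix interval in hours.
#' @param move_threshold Moving/not-moving step-length threshold, metres.
#'   Steps longer than this are "moving".
#' @return An object of class `movement_params`.
#' @export
#' @examples
#' movement_params("December", 3013, 2657, 162, 12283, -2.46, 103.85)
movement_params <- function(month, step_mean, step_sd,
                            step_min = NA_real_, step_max = Inf,
                            turn_mean = 0, turn_sd = 104,
                            p_move = 0.57, step_interval = 2,
                            move_threshold = 150) {
  stopifnot(
    is.numeric(step_mean), step_mean > move_threshold,
    is.numeric(step_sd), step_sd >= 0,
    p_move >= 0, p_move <= 1, turn_sd >= 0
  )
  if (is.finite(step_max) && step_max <= move_threshold) {
    stop("`step_max` must exceed `move_threshold`", call. = FALSE)
  }
  ln <- calibrate_trunc_lnorm(step_mean, step_sd, move_threshold, step_max)
  structure(
    list(
      month = as.character(month),
      step_mean = step_mean, step_sd = step_sd,
      step_min = step_min, step_max = step_max,
      turn_mean = turn_mean, turn_sd = turn_sd,
      p_move = p_move, step_interval = step_interval,
      move_threshold = move_threshold,
      meanlog = ln$meanlog, sdlog = ln$sdlog
    ),
    class = "movement_params"
  )
}

#' @describeIn movement_params December parameters for GPS-collared wolves
#'   (long movements: mean moving step 3,013 m, SD 2,657 m, observed range
#'   162-12,283 m, turning angle mean -2.46 deg, SD 103.85 deg).
#' @export
december_params <- function() {
  movement_params("December", 3013, 2657, 162, 12283, -2.46, 103.85)
}

#' @describeIn movement_params February parameters (short movements: mean
#'   1,488 m, SD 1,606 m, range 151-11,843 m, turning angle mean 0.48 deg,
#'   SD 105.12 deg).
#' @export
february_params <- function() {
  movement_params("February", 1488, 1606, 151, 11843, 0.48, 105.12)
}

# Log-normal parameters by method of moments on the natural scale.
lnorm_moments <- function(mean, sd) {
  sdlog2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

# Mean and SD of a log-normal truncated to [lo, hi].
trunc_lnorm_moments <- function(meanlog, sdlog, lo, hi) {
  if (sdlog <= 0) {
    m <- exp(meanlog)
    return(list(mean = m, sd = 0))
  }
  a <- (log(lo) - meanlog) / sdlog
  b <- if (is.finite(hi)) (log(hi) - meanlog) / sdlog else Inf
  z <- stats::pnorm(b) - stats::pnorm(a)
  m1 <- exp(meanlog + sdlog^2 / 2) *
    (stats::pnorm(b - sdlog) - stats::pnorm(a - sdlog)) / z
  m2 <- exp(2 * meanlog + 2 * sdlog^2) *
    (stats::pnorm(b - 2 * sdlog) - stats::pnorm(a - 2 * sdlog)) / z
  list(mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
}

# Solve (meanlog, sdlog) so the [lo, hi]-truncated log-normal has the target
# natural-scale mean and SD. Initialized at the untruncated method-of-moments
# solution; with no effective truncation the solve returns it unchanged.
calibrate_trunc_lnorm <- function(mean, sd, lo, hi) {
  if (sd == 0) return(list(meanlog = log(mean), sdlog = 0))
  mom <- lnorm_moments(mean, sd)
  if (!is.finite(hi)) return(mom)
  obj <- function(par) {
    mm <- trunc_lnorm_moments(par[1], exp(par[2]), lo, hi)
    (mm$mean / mean - 1)^2 + (mm$sd / sd - 1)^2
  }
  fit <- stats::optim(c(mom$meanlog, log(mom$sdlog)), obj,
                      control = list(reltol = 1e-12, maxit = 2000))
  list(meanlog = fit$par[1], sdlog = exp(fit$par[2]))
}

# Quantile sampler for the truncated moving-step length distribution.
rtrunc_lnorm <- function(n, params) {
  if (params$sdlog == 0) return(rep(params$step_mean, n))
  lo <- stats::plnorm(params$move_threshold, params$meanlog, params$sdlog)
  hi <- if (is.finite(params$step_max)) {
    stats::plnorm(params$step_max, params$meanlog, params$sdlog)
  } else 1
  stats::qlnorm(stats::runif(n, lo, hi), params$meanlog, params$sdlog)
}

#' @export
print.movement_params <- function(x, ...) {
  cat(sprintf(
    "<movement_params: %s>\n  moving step: mean %.0f m, sd %.0f m, range [%s, %s] m\n  turning angle: mean %.2f deg, sd %.2f deg\n  p(move) per %g-h step: %.2f (threshold %g m)\n",
    x$month, x$step_mean, x$step_sd,
    ifelse(is.na(x$step_min), "?", format(x$step_min)),
    ifelse(is.finite(x$step_max), format(x$step_max), "Inf"),
    x$turn_mean, x$turn_sd, x$step_interval, x$p_move, x$move_threshold
  ))
  invisible(x)
}

#' Tidy a movement parameter set
#'
#' @param x A `movement_params` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`, `unit`).
#' @method tidy movement_params
#' @export
tidy.movement_params <- function(x, ...) {
  tibble::tibble(
    term = c("step_mean", "step_sd", "step_min", "step_max", "turn_mean",
             "turn_sd", "p_move", "step_interval", "move_threshold",
             "meanlog", "sdlog"),
    estimate = c(x$step_mean, x$step_sd, x$step_min, x$step_max, x$turn_mean,
                 x$turn_sd, x$p_move, x$step_interval, x$move_threshold,
                 x$meanlog, x$sdlog),
    unit = c("m", "m", "m", "m", "deg", "deg", "probability", "h", "m",
             "log(m)", "log(m)")
  )
}

#' Glance at a movement parameter set
#'
#' @inheritParams tidy.movement_params
#' @return A one-row tibble.
#' @method glance movement_params
#' @export
glance.movement_params <- function(x, ...) {
  n_steps <- attr(x, "n_steps")
  n_moving <- attr(x, "n_moving")
  tibble::tibble(
    month = x$month,
    n_steps = if (is.null(n_steps)) NA_integer_ else n_steps,
    n_moving = if (is.null(n_moving)) NA_integer_ else n_moving,
    step_mean = x$step_mean, step_sd = x$step_sd,
    turn_mean = x$turn_mean, turn_sd = x$turn_sd, p_move = x$p_move
  )
}
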
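# Two-state, habitat-biased correlated random walk for 2-day wolf paths.
#
# Each 2-h step is "moving" with probability p_move (independent Bernoulli;
# only the marginal activity fraction is known empirically). Moving steps
# draw K candidate (length, bearing) pairs - truncated log-normal lengths,
# wrapped-normal turning angles about the current heading - score each
# candidate by the habitat weight at its endpoint (zero outside the owning
# territory), and keep one by roulette selection. Not-moving steps displace
# < 150 m with uniform heading and do not reset the CRW heading.

as_territory <- function(territory) {
  if (is.null(territory)) return(NULL)
  if (is.data.frame(territory)) {
    stopifnot(nrow(territory) == 1)
    return(list(cx = territory$cx, cy = territory$cy,
                radius = territory$radius_m %||% territory$radius))
  }
  stopifnot(is.list(territory), !is.null(territory$cx), !is.null(territory$cy))
  list(cx = territory$cx, cy = territory$cy,
       radius = territory$radius %||% territory$radius_m)
}

# Uniform points in discs (vectorized over centres).
runif_disc <- function(n, cx, cy, radius) {
  r <- radius * sqrt(stats::runif(n))
  a <- stats::runif(n, 0, 2 * pi)
  cbind(cx + r * cos(a), cy + r * sin(a))
}

#' Draw one step of the two-state movement model
#'
#' The marginal (landscape-free) step draw: state is Bernoulli(`p_move`);
#' moving steps get a truncated log-normal length and a bearing equal to
#' `prev_bearing` plus a wrapped-normal turning angle (uniform bearing when
#' `prev_bearing` is `NA`); not-moving steps get a Uniform[0, threshold)
#' length and a uniform bearing.
#'
#' @param prev_bearing Previous heading in degrees, or `NA` for none.
#' @param params A [movement_params] object.
#' @param n Number of independent draws.
#' @return A tibble with columns `state`, `length_m`, `bearing_deg`.
#' @export
draw_step <- function(prev_bearing, params, n = 1) {
  stopifnot(inherits(params, "movement_params"))
  moving <- stats::runif(n) < params$p_move
  length_m <- bearing <- numeric(n)
  n_mv <- sum(moving)
  if (n_mv > 0) {
    length_m[moving] <- rtrunc_lnorm(n_mv, params)
    turn <- stats::rnorm(n_mv, params$turn_mean, params$turn_sd)
    base <- if (is.na(prev_bearing)) stats::runif(n_mv, -180, 180) else prev_bearing
    bearing[moving] <- wrap_deg(base + turn)
  }
  if (n_mv < n) {
    length_m[!moving] <- stats::runif(n - n_mv, 0, params$move_threshold)
    bearing[!moving] <- stats::runif(n - n_mv, -180, 180)
  }
  tibble::tibble(
    state = ifelse(moving, "moving", "not_moving"),
    length_m = length_m, bearing_deg = bearing
  )
}

# Core batched simulator. `territory` is NULL (unconstrained) or a list of
# vectors cx, cy, radius of length n (one owning circle per path).
# Returns list(x, y: n x (n_steps+1) matrices; state: n x n_steps logical
# matrix, TRUE = moving; rejections: count of resimulated paths).
simulate_paths_batch <- function(n, start, territory, params, landscape,
                                 n_steps = 24, n_candidates = 20,
                                 max_retries = 10, .depth = 0) {
  stopifnot(n >= 1, n_steps >= 1)
  K <- n_candidates
  X <- matrix(NA_real_, n, n_steps + 1)
  Y <- matrix(NA_real_, n, n_steps + 1)
  S <- matrix(FALSE, n, n_steps)
  X[, 1] <- start[, 1]; Y[, 1] <- start[, 2]
  heading <- stats::runif(n, -180, 180)
  rejected <- logical(n)
  thr <- params$move_threshold
  for (s in seq_len(n_steps)) {
    cx <- X[, s]; cy <- Y[, s]
    moving <- stats::runif(n) < params$p_move
    S[, s] <- moving
    nx <- cx; ny <- cy
    m <- which(moving & !rejected)
    if (length(m) > 0) {
      active <- m
      head_a <- heading[active]
      tries <- 0
      while (length(active) > 0) {
        na <- length(active)
        turn <- matrix(stats::rnorm(na * K, params$turn_mean, params$turn_sd), na, K)
        len <- matrix(rtrunc_lnorm(na * K, params), na, K)
        brg <- wrap_deg(head_a + turn)
        ex <- X[active, s] + len * cos(deg2rad(brg))
        ey <- Y[active, s] + len * sin(deg2rad(brg))
        score <- if (is.null(landscape)) {
          matrix(1, na, K)
        } else {
          matrix(landscape_value(landscape, as.vector(ex), as.vector(ey)), na, K)
        }
        if (!is.null(territory)) {
          tcx <- territory$cx[active]; tcy <- territory$cy[active]
          tr <- territory$radius[active]
          inside <- (ex - tcx)^2 + (ey - tcy)^2 <= tr^2
          score[!inside] <- 0
        }
        tot <- rowSums(score)
        ok <- tot > 0
        if (any(ok)) {
          io <- which(ok)
          probs <- score[io, , drop = FALSE] / tot[io]
          cum <- probs %*% upper.tri(diag(K), diag = TRUE)
          u <- stats::runif(length(io))
          sel <- rowSums(cum < u) + 1L
          pick <- cbind(io, sel)
          rows <- active[io]
          nx[rows] <- ex[pick]
          ny[rows] <- ey[pick]
          heading[rows] <- brg[pick]
        }
        if (all(ok)) break
        tries <- tries + 1
        fail <- which(!ok)
        if (tries > max_retries) {
          rejected[active[fail]] <- TRUE
          break
        }
        # reflect heading toward the territory centre and redraw
        rows <- active[fail]
        head_a <- bearing_deg(territory$cx[rows] - X[rows, s],
                              territory$cy[rows] - Y[rows, s])
        active <- rows
      }
    }
    nm <- which(!moving & !rejected)
    if (length(nm) > 0) {
      dr <- stats::runif(length(nm), 0, thr)
      ang <- deg2rad(stats::runif(length(nm), -180, 180))
      px <- cx[nm] + dr * cos(ang)
      py <- cy[nm] + dr * sin(ang)
      if (!is.null(territory)) {
        for (tr_i in 1:50) {
          out <- (px - territory$cx[nm])^2 + (py - territory$cy[nm])^2 >
            territory$radius[nm]^2
          if (!any(out)) break
          k <- sum(out)
          d2 <- stats::runif(k, 0, thr); a2 <- deg2rad(stats::runif(k, -180, 180))
          px[out] <- cx[nm][out] + d2 * cos(a2)
          py[out] <- cy[nm][out] + d2 * sin(a2)
        }
        still_out <- (px - territory$cx[nm])^2 + (py - territory$cy[nm])^2 >
          territory$radius[nm]^2
        px[still_out] <- cx[nm][still_out]
        py[still_out] <- cy[nm][still_out]
      }
      nx[nm] <- px; ny[nm] <- py
      # heading deliberately not updated: stationary jitter does not reset
      # directional persistence
    }
    X[, s + 1] <- nx; Y[, s + 1] <- ny
  }
  n_rejected <- sum(rejected)
  if (n_rejected > 0) {
    if (.depth >= 5) {
      stop("unrecoverable territory confinement failure after repeated resimulation",
           call. = FALSE)
    }
    idx <- which(rejected)
    terr_sub <- if (is.null(territory)) NULL else {
      list(cx = territory$cx[idx], cy = territory$cy[idx],
           radius = territory$radius[idx])
    }
    new_start <- if (is.null(terr_sub)) {
      cbind(start[idx, 1], start[idx, 2])
    } else {
      runif_disc(length(idx), terr_sub$cx, terr_sub$cy, terr_sub$radius)
    }
    redo <- simulate_paths_batch(length(idx), new_start, terr_sub, params,
                                 landscape, n_steps, K, max_retries,
                                 .depth = .depth + 1)
    X[idx, ] <- redo$x; Y[idx, ] <- redo$y; S[idx, ] <- redo$state
    n_rejected <- n_rejected + redo$rejections
  }
  list(x = X, y = Y, state = S, rejections = n_rejected)
}

# Long tidy tibble from a batch result.
tidy_paths <- function(sim, path_id = seq_len(nrow(sim$x)),
                       pack_id = NA_integer_, owner = "pack",
                       draw = NA_integer_) {
  n <- nrow(sim$x); n_v <- ncol(sim$x)
  tibble::tibble(
    path_id = rep(path_id, each = n_v),
    owner = rep(owner, length.out = n)[rep(seq_len(n), each = n_v)],
    pack_id = rep(pack_id, length.out = n)[rep(seq_len(n), each = n_v)],
    draw = rep(draw, length.out = n)[rep(seq_len(n), each = n_v)],
    step = rep(0:(n_v - 1), times = n),
    x_m = as.vector(t(sim$x)),
    y_m = as.vector(t(sim$y)),
    state = c(rbind(NA, t(ifelse(sim$state, "moving", "not_moving"))))
  )
}

#' Simulate one 2-day wolf travel path
#'
#' Runs the two-state, habitat-biased correlated random walk for `n_steps`
#' two-hour steps (24 = 48 h). Pack paths start uniformly inside their
#' territory circle and every vertex is confined to it; with `territory =
#' NULL` the walk is unconstrained (lone wolf). With `landscape = NULL`
#' (flat habitat) candidate selection is uniform and the walk reduces to an
#' unbiased CRW.
#'
#' @param territory `NULL`, a one-row layout tibble, or
#'   `list(cx =, cy =, radius =)` in metres.
#' @param params A [movement_params] object.
#' @param landscape A `landscape_raster` or `NULL`.
#' @param n_steps Number of steps (24 for a 2-day path at 2-h fixes).
#' @param start Optional start coordinate `c(x, y)`; default uniform in the
#'   territory (or at the origin when unconstrained).
#' @param n_candidates Candidate steps scored per moving step (habitat bias
#'   strength; 1 recovers the unbiased CRW exactly).
#' @param seed Optional integer seed.
#' @return A tibble with columns `path_id`, `owner`, `pack_id`, `draw`,
#'   `step` (0..`n_steps`), `x_m`, `y_m`, `state` (`NA` at step 0).
#' @export
simulate_path <- function(territory = NULL, params = december_params(),
                          landscape = NULL, n_steps = 24, start = NULL,
                          n_candidates = 20, seed = NULL) {
  stopifnot(n_steps >= 1)
  terr <- as_territory(territory)
  if (!is.null(seed)) set.seed(substream_seed(seed, "path"))
  if (is.null(start)) {
    start <- if (is.null(terr)) c(0, 0) else {
      runif_disc(1, terr$cx, terr$cy, terr$radius)[1, ]
    }
  }
  sim <- simulate_paths_batch(
    1, matrix(start, 1), terr, params, landscape, n_steps, n_candidates
  )
  out <- tidy_paths(sim, owner = if (is.null(terr)) "loner" else "pack")
  attr(out, "rejections") <- sim$rejections
  out
}

#' Simulate a library of paths for every territory in a layout
#'
#' `n_paths` 2-day paths per territory (1,000 per territory and month in the
#' reference design), from which virtual surveys later draw each pack's
#' realized track networks.
#'
#' @param layout A `territory_layout` tibble from [layout_territories()].
#' @param params A [movement_params] object.
#' @param landscape A `landscape_raster` or `NULL` (flat habitat).
#' @param n_paths Paths per territory.
#' @param seed Integer seed; libraries are reproducible given the seed.
#' @param n_candidates Candidate steps per moving step.
#' @param n_steps Steps per path.
#' @return A tibble of vertices (`path_id` unique across the library,
#'   `pack_id`, `draw` = index of the path within its territory, `step`,
#'   `x_m`, `y_m`, `state`), with attribute `rejections`.
#' @export
generate_path_library <- function(layout, params = december_params(),
                                  landscape = NULL, n_paths = 1000,
                                  seed = 1L, n_candidates = 20, n_steps = 24) {
  stopifnot(nrow(layout) > 0, n_paths >= 1)
  set.seed(substream_seed(seed, "library", params$month))
  n_t <- nrow(layout)
  n <- n_t * n_paths
  terr <- list(
    cx = rep(layout$cx, each = n_paths),
    cy = rep(layout$cy, each = n_paths),
    radius = rep(layout$radius_m, each = n_paths)
  )
  start <- runif_disc(n, terr$cx, terr$cy, terr$radius)
  sim <- simulate_paths_batch(n, start, terr, params, landscape, n_steps,
                              n_candidates)
  out <- tidy_paths(
    sim,
    path_id = seq_len(n),
    pack_id = rep(layout$pack_id, each = n_paths),
    draw = rep(seq_len(n_paths), times = n_t)
  )
  attr(out, "rejections") <- sim$rejections
  attr(out, "n_paths") <- n_paths
  out
}

#' Simulate unconstrained lone-wolf paths
#'
#' Same movement model as pack paths but with no territory constraint:
#' paths start uniformly within the extent and may leave it (the habitat
#' raster is padded so endpoints remain scorable).
#'
#' @param extent Numeric `c(xmin, xmax, ymin, ymax)` in metres.
#' @param params A [movement_params] object.
#' @param n_loners Number of lone wolves (>= 0).
#' @param landscape A `landscape_raster` or `NULL`.
#' @param seed Integer seed.
#' @param n_candidates,n_steps As in [generate_path_library()].
#' @return A tibble of vertices with `owner = "loner"`; zero rows when
#'   `n_loners = 0`.
#' @export
simulate_loner_paths <- function(extent, params = december_params(),
                                 n_loners = 0, landscape = NULL, seed = 1L,
                                 n_candidates = 20, n_steps = 24) {
  stopifnot(n_loners >= 0)
  extent <- check_extent(extent)
  if (n_loners == 0) {
    return(tibble::tibble(
      path_id = integer(), owner = character(), pack_id = integer(),
      draw = integer(), step = integer(), x_m = double(), y_m = double(),
      state = character()
    ))
  }
  set.seed(substream_seed(seed, "loners", params$month))
  start <- cbind(stats::runif(n_loners, extent[["xmin"]], extent[["xmax"]]),
                 stats::runif(n_loners, extent[["ymin"]], extent[["ymax"]]))
  sim <- simulate_paths_batch(n_loners, start, NULL, params, landscape,
                              n_steps, n_candidates)
  tidy_paths(sim, owner = "loner")
}
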
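# Path-characteristic statistics used to validate simulated movements:
# total length, survey units intersected per grid, and crossings of linear
# landscape features, compared between matched path sets with paired
# t-tests.

# TRUE iff open segments (p1,p2) and (p3,p4) cross transversally (shared
# endpoints / collinear overlap do not count as crossings).
segments_cross <- function(x1, y1, x2, y2, x3, y3, x4, y4) {
  d1 <- (x4 - x3) * (y1 - y3) - (y4 - y3) * (x1 - x3)
  d2 <- (x4 - x3) * (y2 - y3) - (y4 - y3) * (x2 - x3)
  d3 <- (x2 - x1) * (y3 - y1) - (y2 - y1) * (x3 - x1)
  d4 <- (x2 - x1) * (y4 - y1) - (y2 - y1) * (x4 - x1)
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

# Number of transversal crossing points between a path polyline and a
# feature polyline (each crossing counted once).
count_polyline_crossings <- function(px, py, fx, fy) {
  n_p <- length(px) - 1; n_f <- length(fx) - 1
  if (n_p < 1 || n_f < 1) return(0L)
  total <- 0L
  for (i in seq_len(n_p)) {
    hit <- segments_cross(px[i], py[i], px[i + 1], py[i + 1],
                          fx[-length(fx)], fy[-length(fy)], fx[-1], fy[-1])
    total <- total + sum(hit)
  }
  total
}

#' Path characteristics for validation against track surveys
#'
#' Total polyline length, number of distinct cells intersected in each
#' grid, and number of transversal river and road/pipeline crossings.
#'
#' @param paths A path tibble (may hold several paths, keyed by `path_id`).
#' @param grids A named list of `survey_grid` objects (names used as
#'   columns, e.g. `"cells_36"`).
#' @param features A line-feature tibble from [generate_line_features()]
#'   (or zero rows for none).
#' @return A tibble with one row per path: `path_id`, `length_km`, one
#'   cell-count column per grid, `river_crossings`,
#'   `road_pipeline_crossings`.
#' @export
path_characteristics <- function(paths, grids = list(), features = NULL) {
  stopifnot(nrow(paths) > 0)
  if (is.null(features)) {
    features <- tibble::tibble(kind = character(), feature_id = integer(),
                               x_m = double(), y_m = double())
  }
  feat_split <- split(features[c("kind", "x_m", "y_m")], features$feature_id)
  purrr::map_dfr(split(paths, paths$path_id), function(p) {
    p <- p[order(p$step), ]
    if (nrow(p) < 2) stop("a path needs >= 2 vertices", call. = FALSE)
    dx <- diff(p$x_m); dy <- diff(p$y_m)
    row <- tibble::tibble(path_id = p$path_id[1],
                          length_km = sum(sqrt(dx^2 + dy^2)) / 1000)
    for (g in names(grids)) {
      row[[g]] <- length(cell_intersections(p, grids[[g]]))
    }
    river <- 0L; roadpipe <- 0L
    for (f in feat_split) {
      k <- count_polyline_crossings(p$x_m, p$y_m, f$x_m, f$y_m)
      if (f$kind[1] == "river") river <- river + k else roadpipe <- roadpipe + k
    }
    row$river_crossings <- river
    row$road_pipeline_crossings <- roadpipe
    row
  })
}

#' Compare two matched sets of path characteristics
#'
#' Paired t-test per characteristic between two equally sized,
#' start-matched path-statistics tables (the real-vs-simulated validation
#' design, here runnable simulator-vs-simulator). Characteristics with
#' identical paired values give `statistic = 0`, `p_value = 1`.
#'
#' @param stats_a,stats_b Tibbles from [path_characteristics()], matched
#'   row for row.
#' @return A tibble with one row per characteristic: `characteristic`,
#'   `mean_a`, `sd_a`, `mean_b`, `sd_b`, `statistic`, `p_value`.
#' @export
paired_path_comparison <- function(stats_a, stats_b) {
  if (nrow(stats_a) != nrow(stats_b)) {
    stop("path sets must be matched: unequal lengths", call. = FALSE)
  }
  chars <- setdiff(intersect(names(stats_a), names(stats_b)), "path_id")
  purrr::map_dfr(chars, function(ch) {
    a <- stats_a[[ch]]; b <- stats_b[[ch]]
    d <- a - b
    if (stats::sd(d) <= 1e-8 * max(1, abs(mean(d)))) {
      # constant differences: identical sets compare equal, a pure shift is
      # detected with certainty
      stat <- if (isTRUE(all.equal(mean(d), 0))) 0 else sign(mean(d)) * Inf
      pv <- if (stat == 0) 1 else 0
    } else {
      tt <- stats::t.test(a, b, paired = TRUE)
      stat <- unname(tt$statistic); pv <- tt$p.value
    }
    tibble::tibble(characteristic = ch,
                   mean_a = mean(a), sd_a = stats::sd(a),
                   mean_b = mean(b), sd_b = stats::sd(b),
                   statistic = stat, p_value = pv)
  })
}
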
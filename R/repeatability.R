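#' Dynamic time warping dissimilarity between two tracks
#'
#' Classic DTW: the smallest cumulative pointwise distance over all monotone,
#' boundary-matched alignments of the two position sequences, with single-step
#' moves (i-1,j), (i,j-1), (i-1,j-1) and no warping window. Because the
#' alignment may repeat points, DTW compares tracks of different speeds and
#' lengths; larger values mean more dissimilar routes. The pointwise metric is
#' Euclidean distance in a common projected plane (km) when the segments are
#' `x_km`/`y_km` matrices, or great-circle km when they carry `lat`/`lon`
#' columns and `metric = "greatcircle"`.
#'
#' @param a,b Two-column matrices or data frames of positions, in track
#'   order: columns `x_km`,`y_km` (planar) or `lat`,`lon` (great-circle).
#' @param metric `"euclidean"` (planar km, default) or `"greatcircle"`.
#' @param normalize Divide the cumulative value by the alignment path length
#'   (default `FALSE`: raw cumulative distance).
#' @return Non-negative DTW dissimilarity (0 for identical segments).
#' @export
dtw_distance <- function(a, b, metric = c("euclidean", "greatcircle"),
                         normalize = FALSE) {
  metric <- match.arg(metric)
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) == 0 || nrow(b) == 0) stop("dtw_distance(): empty segment")
  cost <- dtw_cost_matrix(a, b, metric)
  n <- nrow(cost); m <- ncol(cost)
  d <- matrix(Inf, n + 1, m + 1)
  steps <- matrix(0L, n + 1, m + 1)
  d[1, 1] <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      prev <- min(d[i, j + 1], d[i + 1, j], d[i, j])
      d[i + 1, j + 1] <- cost[i, j] + prev
      if (normalize) {
        k <- which.min(c(d[i, j], d[i, j + 1], d[i + 1, j]))
        steps[i + 1, j + 1] <- 1L + switch(k, steps[i, j], steps[i, j + 1],
                                           steps[i + 1, j])
      }
    }
  }
  if (normalize) d[n + 1, m + 1] / steps[n + 1, m + 1] else d[n + 1, m + 1]
}

dtw_cost_matrix <- function(a, b, metric) {
  if (metric == "euclidean") {
    dx <- outer(a[, 1], b[, 1], "-")
    dy <- outer(a[, 2], b[, 2], "-")
    sqrt(dx^2 + dy^2)
  } else {
    outer(seq_len(nrow(a)), seq_len(nrow(b)), function(i, j) {
      great_circle_km(a[i, 1], a[i, 2], b[j, 1], b[j, 2])
    })
  }
}

#' Seasonal daily-track segments
#'
#' Builds the segments compared by the repeatability analysis: each bird's
#' track is regularized to daily positions, projected into a common Lambert
#' azimuthal equal-area plane (centered on the spherical mean of all fixes
#' unless `center` is given), and split by season band and year. Segments
#' with fewer than two daily positions are dropped.
#'
#' @param fixes A filtered fix tibble.
#' @param center Optional projection center (`lat`, `lon`); default the
#'   cohort spherical mean.
#' @param tz Time zone for season membership of daily positions (default
#'   UTC+9).
#' @return A nested tibble: `bird_id`, `season`, `year`, `n_days`, and
#'   `positions` (list of matrices with columns `x_km`, `y_km`).
#' @export
seasonal_segments <- function(fixes, center = NULL, tz = TZ_KST) {
  center <- center %||% spherical_mean(fixes$lat, fixes$lon)
  reg <- regularize_track(fixes, interval_h = 24)
  xy <- laea_project(reg$lat, reg$lon, center)
  reg |>
    dplyr::mutate(
      x_km = xy$x_km, y_km = xy$y_km,
      date = lubridate::as_date(.data$timestamp, tz = tz),
      season = assign_season(.data$date),
      year = season_year(.data$date)
    ) |>
    dplyr::group_by(.data$bird_id, .data$season, .data$year) |>
    dplyr::arrange(.data$timestamp, .by_group = TRUE) |>
    dplyr::summarise(
      n_days = dplyr::n(),
      positions = list(cbind(x_km = .data$x_km, y_km = .data$y_km)),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_days >= 2)
}

#' Within- and between-individual DTW values for one season
#'
#' All unordered pairs of one season's segments, each evaluated once with
#' [dtw_distance()]: pairs of segments from the same individual in different
#' years form the within-individual group, pairs from different individuals
#' the between-individual group.
#'
#' @param segments Output of [seasonal_segments()].
#' @param season One of `"winter"`, `"spring"`, `"summer"`, `"autumn"`.
#' @inheritParams dtw_distance
#' @return A tibble: `bird_a`, `year_a`, `bird_b`, `year_b`, `value`,
#'   `same_individual`. Empty groups are simply absent.
#' @export
seasonal_dtw_sets <- function(segments, season,
                              metric = c("euclidean", "greatcircle"),
                              normalize = FALSE) {
  metric <- match.arg(metric)
  seg <- dplyr::filter(segments, .data$season == .env$season)
  n <- nrow(seg)
  if (n < 2) {
    return(tibble::tibble(bird_a = character(0), year_a = integer(0),
                          bird_b = character(0), year_b = integer(0),
                          value = numeric(0), same_individual = logical(0)))
  }
  pairs <- utils::combn(n, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    tibble::tibble(
      bird_a = seg$bird_id[i], year_a = seg$year[i],
      bird_b = seg$bird_id[j], year_b = seg$year[j],
      value = dtw_distance(seg$positions[[i]], seg$positions[[j]],
                           metric = metric, normalize = normalize),
      same_individual = seg$bird_id[i] == seg$bird_id[j]
    )
  })
}

#' Permutation test for a difference of group means
#'
#' Randomization inference: the observed statistic is `mean(a) - mean(b)`;
#' under the null the group labels are redistributed at random `n_perm` times
#' and the two-sided p-value is the add-one-smoothed fraction of permuted
#' absolute differences at least as large as the observed one,
#' `(1 + k) / (n_perm + 1)` -- never exactly zero.
#'
#' @param a,b Numeric vectors (e.g. within- and between-individual DTW
#'   values).
#' @param n_perm Number of label permutations (default 10000).
#' @param seed Optional integer seed for exact reproducibility.
#' @return A `perm_test` object: list with `observed_diff`, `p_value`,
#'   `n_perm`, `n_a`, `n_b`, `seed`. Supports [tidy()].
#' @export
permutation_diff_test <- function(a, b, n_perm = 10000, seed = NULL) {
  stopifnot(length(a) > 0, length(b) > 0, n_perm >= 1)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  pooled <- c(a, b)
  na <- length(a)
  obs <- mean(a) - mean(b)
  tot <- sum(pooled)
  nb <- length(b)
  null <- replicate(n_perm, {
    sa <- sum(pooled[sample.int(na + nb, na)])
    sa / na - (tot - sa) / nb
  })
  p <- (1 + sum(abs(null) >= abs(obs) - 1e-12)) / (n_perm + 1)
  structure(list(observed_diff = obs, p_value = p, n_perm = n_perm,
                 n_a = na, n_b = nb, seed = seed),
            class = "perm_test")
}

# Save/restore the global RNG state so seeded helpers do not disturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("permutation test: diff of means = %.4g, p = %.4g (%d permutations)\n",
              x$observed_diff, x$p_value, x$n_perm))
  invisible(x)
}

#' Between-year timing consistency
#'
#' Absolute day-of-year differences between two tracked years of one bird at
#' the start and end of the spring and autumn migratory windows.
#'
#' @param windows Output of [individual_windows()].
#' @param bird Bird id.
#' @param year1,year2 The two years to compare.
#' @return A tibble: `season`, `endpoint` (`start`/`end`), `doy_year1`,
#'   `doy_year2`, `abs_diff_days`. Endpoints whose window is missing in
#'   either year are omitted.
#' @export
timing_consistency <- function(windows, bird, year1, year2) {
  w <- dplyr::filter(windows, .data$bird_id == bird)
  purrr::map_dfr(c("spring", "autumn"), function(s) {
    w1 <- dplyr::filter(w, .data$season == s, .data$year == year1)
    w2 <- dplyr::filter(w, .data$season == s, .data$year == year2)
    if (nrow(w1) != 1 || nrow(w2) != 1) return(NULL)
    tibble::tibble(
      season = s,
      endpoint = c("start", "end"),
      doy_year1 = c(lubridate::yday(w1$first_active), lubridate::yday(w1$last_active)),
      doy_year2 = c(lubridate::yday(w2$first_active), lubridate::yday(w2$last_active))
    ) |>
      dplyr::mutate(abs_diff_days = abs(.data$doy_year2 - .data$doy_year1))
  })
}
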
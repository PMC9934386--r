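#' Mean bout altitude
#'
#' Mean of the start and end altitudes of a bout after flooring negative GPS
#' altitudes at zero (altitudes a few meters below sea level are measurement
#' noise over water).
#'
#' @param start_alt,end_alt Endpoint altitudes in meters (vectorized). `NA`
#'   in either endpoint yields `NA`.
#' @return Mean altitude in meters, `>= 0`.
#' @export
bout_altitude <- function(start_alt, end_alt) {
  (pmax(start_alt, 0) + pmax(end_alt, 0)) / 2
}

#' Extract standardized 2 h bouts
#'
#' Builds one candidate bout per consecutive fix pair and retains those whose
#' duration falls within `duration_range` hours (default 1.9-2.1, the
#' tolerance around a 2 h duty cycle). Each retained bout carries its
#' great-circle distance, rate of travel, floored mean altitude (`NA` when an
#' endpoint altitude is missing), diel class from the apparent solar
#' elevation at each endpoint's own position and instant, migration flag
#' (strictly more than `migration_km` km moved), and calendar month of the
#' start fix in UTC+9.
#'
#' @param fixes A filtered fix tibble (typically subsample B: 2 h duty
#'   cycle).
#' @param duration_range Length-2 numeric, hours (default `c(1.9, 2.1)`).
#' @param migration_km Distance above which a bout is a migration bout
#'   (default 5, strict `>`).
#' @param diel_threshold_deg Solar elevation threshold for night (default
#'   -6, civil twilight).
#' @param tz Time zone assigning the bout month (default UTC+9).
#' @return A bout tibble: `bird_id`, `start_time`, `end_time`, `duration_h`,
#'   `distance_km`, `rate_kmh`, `altitude_m`, `diel`, `is_migration`,
#'   `month`.
#' @export
extract_bouts <- function(fixes, duration_range = c(1.9, 2.1),
                          migration_km = 5, diel_threshold_deg = -6,
                          tz = TZ_KST) {
  steps <- step_table(fixes) |>
    dplyr::filter(.data$dt_h >= duration_range[1], .data$dt_h <= duration_range[2])
  if (nrow(steps) == 0) {
    return(tibble::tibble(
      bird_id = character(0), start_time = as.POSIXct(character(0), tz = "UTC"),
      end_time = as.POSIXct(character(0), tz = "UTC"), duration_h = numeric(0),
      distance_km = numeric(0), rate_kmh = numeric(0), altitude_m = numeric(0),
      diel = character(0), is_migration = logical(0), month = integer(0)))
  }
  steps |>
    dplyr::mutate(
      elev1 = solar_elevation(.data$lat1, .data$lon1, .data$t1),
      elev2 = solar_elevation(.data$lat2, .data$lon2, .data$t2)
    ) |>
    dplyr::transmute(
      bird_id = .data$bird_id,
      start_time = .data$t1, end_time = .data$t2,
      duration_h = .data$dt_h,
      distance_km = .data$dist_km,
      rate_kmh = .data$dist_km / .data$dt_h,
      altitude_m = bout_altitude(.data$alt1, .data$alt2),
      diel = classify_diel(.data$elev1, .data$elev2, diel_threshold_deg),
      is_migration = .data$dist_km > migration_km,
      month = lubridate::month(lubridate::as_date(.data$t1, tz = tz))
    )
}

#' Monthly diel composition of bouts
#'
#' Per calendar month: the proportion of bouts in each diel class (day,
#' twilight, night) and the underlying counts, either over all bouts or over
#' migration bouts only. Proportions within a month sum to 1. By default
#' bouts are pooled across individuals; `per_bird_weight = TRUE` averages the
#' per-bird monthly proportions instead, weighting birds equally.
#'
#' @param bouts Output of [extract_bouts()].
#' @param subset `"all"` or `"migration_only"`.
#' @param per_bird_weight Weight birds equally instead of pooling bouts
#'   (default `FALSE`).
#' @return A tibble: `month`, `diel`, `n` (0 for per-bird weighting), `prop`.
#' @export
diel_composition <- function(bouts, subset = c("all", "migration_only"),
                             per_bird_weight = FALSE) {
  subset <- match.arg(subset)
  if (subset == "migration_only") bouts <- dplyr::filter(bouts, .data$is_migration)
  lv <- c("day", "twilight", "night")
  if (!per_bird_weight) {
    bouts |>
      dplyr::count(.data$month, diel = factor(.data$diel, levels = lv),
                   .drop = FALSE, name = "n") |>
      dplyr::group_by(.data$month) |>
      dplyr::mutate(prop = .data$n / sum(.data$n)) |>
      dplyr::ungroup() |>
      dplyr::mutate(diel = as.character(.data$diel))
  } else {
    bouts |>
      dplyr::count(.data$bird_id, .data$month,
                   diel = factor(.data$diel, levels = lv), .drop = FALSE,
                   name = "n") |>
      dplyr::group_by(.data$bird_id, .data$month) |>
      dplyr::mutate(prop = .data$n / sum(.data$n)) |>
      dplyr::ungroup() |>
      dplyr::group_by(.data$month, .data$diel) |>
      dplyr::summarise(n = sum(.data$n), prop = mean(.data$prop), .groups = "drop") |>
      dplyr::mutate(diel = as.character(.data$diel))
  }
}

# Z statistic (normal deviate with continuity correction and tie-corrected
# variance) for a Mann-Whitney U statistic.
mw_z <- function(u, x, y) {
  n1 <- length(x); n2 <- length(y)
  mu <- n1 * n2 / 2
  nties <- table(c(x, y))
  n <- n1 + n2
  sig2 <- n1 * n2 / 12 * ((n + 1) - sum(nties^3 - nties) / (n * (n - 1)))
  if (sig2 <= 0) return(0)
  (u - mu - 0.5 * sign(u - mu)) / sqrt(sig2)
}

#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test for a difference between
#' two independent groups, as used to compare rates of travel and flight
#' altitudes between months, diel classes and migration vs other bouts. The
#' p-value comes from [stats::wilcox.test()]: exact enumeration when both
#' groups have at most `exact_max` observations and there are no ties,
#' otherwise the normal approximation with tie and continuity corrections.
#' The reported `statistic_z` is the continuity-corrected normal deviate of
#' the U statistic (the form in which such tests are usually quoted).
#'
#' @param x,y Numeric vectors (the two groups), non-empty.
#' @param exact_max Largest per-group n for exact enumeration (default 8).
#' @return A `rank_test` object: list with `test`, `statistic_u`,
#'   `statistic_z`, `p_value`, `n1`, `n2`. Supports [tidy()] and [glance()].
#' @export
mann_whitney <- function(x, y, exact_max = 8) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) == 0 || length(y) == 0) stop("mann_whitney(): empty group")
  ties <- anyDuplicated(c(x, y)) > 0
  if (length(unique(c(x, y))) == 1) {
    res <- list(u = length(x) * length(y) / 2, p = 1)
  } else {
    exact <- !ties && length(x) <= exact_max && length(y) <= exact_max
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE))
    res <- list(u = unname(wt$statistic), p = wt$p.value)
  }
  structure(list(
    test = "mann_whitney_u",
    statistic_u = res$u,
    statistic_z = mw_z(res$u, x, y),
    p_value = res$p,
    n1 = length(x), n2 = length(y)
  ), class = "rank_test")
}

#' Wilcoxon signed rank test
#'
#' Two-sided paired test used to compare medians between paired spring and
#' autumn values per bird. Zero differences are dropped before ranking
#' (Wilcoxon's original treatment). Exact when at most `exact_max` nonzero
#' differences and no tied absolute differences; otherwise normal
#' approximation with continuity correction, via [stats::wilcox.test()].
#'
#' @param x Numeric vector: paired differences, or first member of each pair
#'   when `y` is given.
#' @param y Optional second member of each pair.
#' @param exact_max Largest n for exact enumeration (default 49, the
#'   convention of [stats::wilcox.test()]).
#' @return A `rank_test` object (see [mann_whitney()]); `n1` is the number of
#'   nonzero differences, `n2` is `NA`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 49) {
  d <- if (is.null(y)) x else x - y
  d <- d[is.finite(d)]
  d <- d[d != 0]
  if (length(d) == 0) {
    return(structure(list(test = "wilcoxon_signed_rank", statistic_v = NA_real_,
                          statistic_z = 0, p_value = 1, n1 = 0L, n2 = NA_integer_),
                     class = "rank_test"))
  }
  ties <- anyDuplicated(abs(d)) > 0
  exact <- !ties && length(d) <= exact_max
  wt <- suppressWarnings(stats::wilcox.test(d, exact = exact, correct = TRUE))
  v <- unname(wt$statistic)
  n <- length(d)
  mu <- n * (n + 1) / 4
  r <- rank(abs(d))
  tt <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tt^3 - tt) / 48
  z <- if (sig2 > 0) (v - mu - 0.5 * sign(v - mu)) / sqrt(sig2) else 0
  structure(list(
    test = "wilcoxon_signed_rank",
    statistic_v = v, statistic_z = z, p_value = wt$p.value,
    n1 = n, n2 = NA_integer_
  ), class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("%s: Z = %.3f, p = %.4g (n = %s%s)\n",
              x$test, x$statistic_z, x$p_value, x$n1,
              if (is.na(x$n2)) "" else paste0(", ", x$n2)))
  invisible(x)
}
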
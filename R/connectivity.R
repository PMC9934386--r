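#' Per-bird breeding and wintering centroids
#'
#' Builds the input of the migratory connectivity analysis: for each bird,
#' the spherical mean of its summer-band fixes (breeding-area centroid) and
#' of its winter-band fixes (wintering-area centroid). Birds lacking fixes in
#' either season are excluded.
#'
#' @param fixes A filtered fix tibble (typically subsample A).
#' @param tz Time zone for season membership (default UTC+9).
#' @return A tibble: `bird_id`, `breeding_lat`, `breeding_lon`,
#'   `wintering_lat`, `wintering_lon`.
#' @export
connectivity_input <- function(fixes, tz = TZ_KST) {
  fx <- fixes |>
    dplyr::mutate(season = assign_season(lubridate::as_date(.data$timestamp, tz = tz)))
  cent <- function(df) spherical_mean(df$lat, df$lon)
  fx |>
    dplyr::filter(.data$season %in% c("summer", "winter")) |>
    dplyr::group_by(.data$bird_id, .data$season) |>
    dplyr::summarise(lat = cent(dplyr::pick(dplyr::everything()))$lat,
                     lon = cent(dplyr::pick(dplyr::everything()))$lon,
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "season", values_from = c("lat", "lon")) |>
    dplyr::filter(!is.na(.data$lat_summer), !is.na(.data$lat_winter)) |>
    dplyr::transmute(
      bird_id = .data$bird_id,
      breeding_lat = .data$lat_summer, breeding_lon = .data$lon_summer,
      wintering_lat = .data$lat_winter, wintering_lon = .data$lon_winter
    )
}

# Pairwise great-circle distance matrix over rows of (lat, lon).
pairwise_gc_matrix <- function(lat, lon) {
  n <- length(lat)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    m[i, ] <- great_circle_km(lat[i], lon[i], lat, lon)
  }
  m
}

mantel_r <- function(d1, d2) {
  low <- lower.tri(d1)
  a <- d1[low]; b <- d2[low]
  if (sd(a) == 0 || sd(b) == 0) {
    stop("mantel_connectivity(): zero variance in a distance matrix; r undefined")
  }
  cor(a, b)
}

#' Mantel test of migratory connectivity
#'
#' Migratory connectivity as the Mantel correlation between the pairwise
#' great-circle distance matrix of the birds' breeding centroids and that of
#' their wintering centroids: the Pearson correlation of the strictly lower
#' triangles. Strong positive r means neighbours on the breeding grounds
#' remain neighbours on the wintering grounds. The 95% confidence interval is
#' estimated by resampling birds with replacement (`n_boot` draws,
#' percentile method); degenerate resamples with fewer than three distinct
#' birds, or with zero variance in either triangle, are redrawn.
#'
#' @param inputs Output of [connectivity_input()] (at least 3 birds).
#' @param n_boot Bootstrap draws (default 1000).
#' @param seed Optional integer seed.
#' @return A `mantel_result` object: list with `r_mantel`, `ci_low`,
#'   `ci_high`, `n_birds`, `n_boot`, `seed`. Supports [tidy()] and
#'   [glance()].
#' @export
mantel_connectivity <- function(inputs, n_boot = 1000, seed = NULL) {
  n <- nrow(inputs)
  if (n < 3) stop("mantel_connectivity(): need at least 3 birds")
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  db <- pairwise_gc_matrix(inputs$breeding_lat, inputs$breeding_lon)
  dw <- pairwise_gc_matrix(inputs$wintering_lat, inputs$wintering_lon)
  r <- mantel_r(db, dw)
  boot <- rep(NA_real_, n_boot)
  if (n_boot > 0) {
    for (k in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(idx)) < 3) next
        low <- lower.tri(db)
        a <- db[idx, idx][low]; b <- dw[idx, idx][low]
        if (sd(a) == 0 || sd(b) == 0) next
        boot[k] <- cor(a, b)
        break
      }
    }
  }
  ci <- if (n_boot > 0) unname(quantile(boot, c(0.025, 0.975))) else c(NA, NA)
  structure(list(r_mantel = r, ci_low = ci[1], ci_high = ci[2],
                 boot = boot, n_birds = n, n_boot = n_boot, seed = seed),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel connectivity: r = %.3f, 95%% CI = %.2f-%.2f (%d birds, %d bootstraps)\n",
              x$r_mantel, x$ci_low, x$ci_high, x$n_birds, x$n_boot))
  invisible(x)
}
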
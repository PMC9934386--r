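#' Plot the daily latitudinal phenology
#'
#' Latitude of each bird's daily mean position over the year, with active
#' migration days highlighted and the activity latitude band marked -- the
#' standard visual check of the displacement-threshold phenology.
#'
#' @param days Output of [classify_active_days()].
#' @param lat_band The latitude band to mark (default `c(40.9, 64.9)`).
#' @return A ggplot object.
#' @export
plot_phenology <- function(days, lat_band = c(40.9, 64.9)) {
  ggplot2::ggplot(days, ggplot2::aes(x = .data$date, y = .data$mean_lat,
                                     group = .data$bird_id)) +
    ggplot2::geom_hline(yintercept = lat_band, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point(data = ~ dplyr::filter(.x, .data$active),
                        colour = "#d1495b", size = 0.8) +
    ggplot2::labs(x = NULL, y = "Daily mean latitude (°N)",
                  title = "Daily latitudinal distribution",
                  subtitle = "red: days of active migration") +
    ggplot2::theme_minimal()
}

#' Plot monthly diel composition of bouts
#'
#' Stacked monthly proportions of day, twilight and night bouts.
#'
#' @param composition Output of [diel_composition()].
#' @return A ggplot object.
#' @export
plot_diel_composition <- function(composition) {
  composition |>
    dplyr::mutate(diel = factor(.data$diel, c("day", "twilight", "night"))) |>
    ggplot2::ggplot(ggplot2::aes(x = factor(.data$month), y = .data$prop,
                                 fill = .data$diel)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(day = "#4477aa", twilight = "#ccaa66",
                                          night = "#555555")) +
    ggplot2::labs(x = "Month", y = "Proportion of bouts", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot within- vs between-individual DTW values by season
#'
#' @param dtw_values A tibble of DTW pairs with `season`, `value`,
#'   `same_individual` (as produced by [run_pipeline()]'s dtw stage).
#' @return A ggplot object.
#' @export
plot_dtw_comparison <- function(dtw_values) {
  dtw_values |>
    dplyr::mutate(
      group = ifelse(.data$same_individual, "within", "between"),
      season = factor(.data$season, c("winter", "spring", "summer", "autumn"))
    ) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$season, y = .data$value,
                                 fill = .data$group)) +
    ggplot2::geom_boxplot(position = ggplot2::position_dodge(preserve = "single")) +
    ggplot2::scale_fill_manual(values = c(within = "white", between = "grey70")) +
    ggplot2::labs(x = NULL, y = "DTW dissimilarity (km)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a utilization distribution
#'
#' Filled density raster in the projected plane with optional isopleth
#' contours.
#'
#' @param object A `ud_grid`.
#' @param levels Isopleth levels to outline (default `c(0.5, 0.95)`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ud_grid <- function(object, levels = c(0.5, 0.95), ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x_km, .data$y_km)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$density)) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)", fill = "UD") +
    ggplot2::theme_minimal()
  for (lv in levels) {
    thr <- min(object$density[isopleth(object, lv)])
    p <- p + ggplot2::geom_contour(ggplot2::aes(z = .data$density),
                                   breaks = thr, colour = "white",
                                   linewidth = 0.3)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
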
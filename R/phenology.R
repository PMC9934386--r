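#' Seasonal bands of the annual cycle
#'
#' Assigns each date to the season band of the gulls' annual cycle: winter
#' (18 Dec - 12 Apr, wrapping the year boundary), spring migration (13 Apr -
#' 6 Jun), summer (7 Jun - 31 Aug) and autumn migration (1 Sep - 17 Dec). The
#' four bands partition the year.
#'
#' @param dates A `Date` vector.
#' @return A character vector: `"winter"`, `"spring"`, `"summer"`, `"autumn"`.
#' @export
assign_season <- function(dates) {
  md <- format(dates, "%m-%d")
  dplyr::case_when(
    md >= "12-18" | md <= "04-12" ~ "winter",
    md <= "06-06" ~ "spring",
    md <= "08-31" ~ "summer",
    TRUE ~ "autumn"
  )
}

# Year label of a season occurrence: the winter band spanning the new year is
# labelled with the January year (18-31 Dec of year Y belongs to winter Y+1).
season_year <- function(dates) {
  yr <- lubridate::year(dates)
  ifelse(format(dates, "%m-%d") >= "12-18", yr + 1L, yr)
}

#' Daily displacement series
#'
#' Collapses a fix table to one record per bird and UTC+9 calendar date:
#' `distance_km` is the sum of consecutive-fix great-circle step distances,
#' each step assigned to the date of its start fix (so a leg starting at
#' 23:00 counts entirely toward that date); `mean_lat`/`mean_lon` are the
#' spherical mean of the date's fixes. Dates without fixes are absent, not
#' zero-filled; days with a single fix and no step starting on them have
#' distance 0.
#'
#' @param fixes A filtered fix tibble.
#' @param tz Time zone defining calendar days (default UTC+9).
#' @return A tibble: `bird_id`, `date`, `n_fixes`, `distance_km`, `mean_lat`,
#'   `mean_lon`.
#' @export
daily_series <- function(fixes, tz = TZ_KST) {
  pos <- fixes |>
    dplyr::mutate(date = lubridate::as_date(.data$timestamp, tz = tz)) |>
    dplyr::group_by(.data$bird_id, .data$date) |>
    dplyr::summarise(
      n_fixes = dplyr::n(),
      mean_lat = spherical_mean(.data$lat, .data$lon)$lat,
      mean_lon = spherical_mean(.data$lat, .data$lon)$lon,
      .groups = "drop"
    )
  steps <- step_table(fixes) |>
    dplyr::mutate(date = lubridate::as_date(.data$t1, tz = tz)) |>
    dplyr::group_by(.data$bird_id, .data$date) |>
    dplyr::summarise(distance_km = sum(.data$dist_km), .groups = "drop")
  pos |>
    dplyr::left_join(steps, by = c("bird_id", "date")) |>
    dplyr::mutate(distance_km = dplyr::coalesce(.data$distance_km, 0)) |>
    dplyr::arrange(.data$bird_id, .data$date)
}

#' Flag days of active migration
#'
#' A day is on active migration when the bird covered strictly more than
#' `min_km` kilometers and its daily mean latitude lay between the northern
#' limit of the wintering range and the southern limit of the breeding sites
#' (defaults 40.9°N and 64.9°N).
#'
#' @param days Output of [daily_series()].
#' @param min_km Daily distance threshold in km (default 60; strict `>`).
#' @param lat_band Length-2 numeric: inclusive latitude band (default
#'   `c(40.9, 64.9)`).
#' @return `days` with logical columns `in_band` and `active` added.
#' @export
classify_active_days <- function(days, min_km = 60, lat_band = c(40.9, 64.9)) {
  days |>
    dplyr::mutate(
      in_band = .data$mean_lat >= lat_band[1] & .data$mean_lat <= lat_band[2],
      active = .data$in_band & .data$distance_km > min_km
    )
}

#' Individual migratory windows
#'
#' Per bird, season and year: the period elapsed between the first and last
#' day of active migration. Active days are split into seasons at the summer
#' band: days before 7 Jun belong to the spring migration of that year, days
#' after 31 Aug to the autumn migration; active days falling inside the
#' summer band (rare within-band movement) belong to neither window.
#'
#' @param days Output of [classify_active_days()].
#' @return A tibble: `bird_id`, `season`, `year`, `first_active`,
#'   `last_active`, `duration_days` (inclusive span), `n_active_days`,
#'   `prop_active`. Bird-season-years without active days are absent.
#' @export
individual_windows <- function(days) {
  act <- dplyr::filter(days, .data$active)
  if (nrow(act) == 0) {
    return(tibble::tibble(
      bird_id = character(0), season = character(0), year = integer(0),
      first_active = as.Date(character(0)), last_active = as.Date(character(0)),
      duration_days = integer(0), n_active_days = integer(0),
      prop_active = numeric(0)))
  }
  act |>
    dplyr::mutate(
      md = format(.data$date, "%m-%d"),
      season = dplyr::case_when(
        .data$md < "06-07" ~ "spring",
        .data$md > "08-31" ~ "autumn",
        TRUE ~ NA_character_
      ),
      year = lubridate::year(.data$date)
    ) |>
    dplyr::filter(!is.na(.data$season)) |>
    dplyr::group_by(.data$bird_id, .data$season, .data$year) |>
    dplyr::summarise(
      first_active = min(.data$date),
      last_active = max(.data$date),
      n_active_days = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      duration_days = as.integer(.data$last_active - .data$first_active) + 1L,
      prop_active = .data$n_active_days / .data$duration_days
    ) |>
    dplyr::select("bird_id", "season", "year", "first_active", "last_active",
                  "duration_days", "n_active_days", "prop_active")
}

#' Population migratory window
#'
#' The period between the first and last recorded day of active migration
#' over all birds combined, for one season and year, together with per-bird
#' activity within it: `prop_active` is each bird's count of active days over
#' the window duration, and `prop_active_monitored` the same count over the
#' days the bird actually has data inside the window (the correction for
#' missing days of monitoring).
#'
#' @param days Output of [classify_active_days()] (all birds).
#' @param season `"spring"` or `"autumn"`.
#' @param year Calendar year of the window.
#' @return A list with `window` (one-row tibble) and `per_bird` (tibble).
#' @export
population_window <- function(days, season, year) {
  iw <- individual_windows(days) |>
    dplyr::filter(.data$season == .env$season, .data$year == .env$year)
  if (nrow(iw) == 0) stop("population_window(): no active days for ",
                          season, " ", year)
  first <- min(iw$first_active)
  last <- max(iw$last_active)
  dur <- as.integer(last - first) + 1L
  inwin <- days |>
    dplyr::filter(.data$date >= first, .data$date <= last)
  per_bird <- inwin |>
    dplyr::group_by(.data$bird_id) |>
    dplyr::summarise(
      n_active_days = sum(.data$active),
      n_monitored_days = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      prop_active = .data$n_active_days / dur,
      prop_active_monitored = .data$n_active_days / .data$n_monitored_days
    )
  list(
    window = tibble::tibble(
      season = season, year = year, first_active = first, last_active = last,
      duration_days = dur, n_active_days = sum(inwin$active),
      n_birds = dplyr::n_distinct(iw$bird_id)
    ),
    per_bird = per_bird
  )
}

#' Fraction of the route covered on active migration days
#'
#' For each individual migratory window: the summed daily distance over the
#' window's active days divided by the summed daily distance over all
#' monitored days inside the window. Values near 1 mean the route is covered
#' almost entirely at high travel rates; the remainder is covered on "off"
#' days (fly-and-forage movement between stopovers).
#'
#' @param days Output of [classify_active_days()].
#' @param windows Output of [individual_windows()].
#' @return `windows` with `route_fraction_active` added (`NA`, flagged via
#'   `route_fraction_defined`, when the window has zero total distance).
#' @export
route_fraction_on_active_days <- function(days, windows) {
  windows |>
    dplyr::rowwise() |>
    dplyr::mutate(
      .tot = sum(days$distance_km[days$bird_id == .data$bird_id &
                                    days$date >= .data$first_active &
                                    days$date <= .data$last_active]),
      .act = sum(days$distance_km[days$bird_id == .data$bird_id &
                                    days$date >= .data$first_active &
                                    days$date <= .data$last_active &
                                    days$active])
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      route_fraction_active = ifelse(.data$.tot > 0, .data$.act / .data$.tot, NA_real_),
      route_fraction_defined = .data$.tot > 0
    ) |>
    dplyr::select(-".tot", -".act")
}

#' Summering class of each bird-year
#'
#' Whether a bird spent the summer band within its breeding range (any summer
#' fix at or above `breeding_lat`), outside it (all summer fixes below
#' `outside_lat`), or mixed (fixes in both regimes, flagged), per calendar
#' year. Bird-years without summer fixes are `"undetermined"`.
#'
#' @param fixes A filtered fix tibble.
#' @param breeding_lat Southern limit of the breeding range (default 64.9).
#' @param outside_lat Latitude below which summering is classed as outside
#'   the breeding range (default 60).
#' @param tz Time zone for calendar dates (default UTC+9).
#' @return A tibble: `bird_id`, `year`, `summering` with values
#'   `"within_breeding_range"`, `"outside_breeding_range"`, `"mixed"`.
#' @export
summering_class <- function(fixes, breeding_lat = 64.9, outside_lat = 60,
                            tz = TZ_KST) {
  dates <- lubridate::as_date(fixes$timestamp, tz = tz)
  fixes |>
    dplyr::mutate(.season = assign_season(dates), .year = lubridate::year(dates)) |>
    dplyr::filter(.data$.season == "summer") |>
    dplyr::group_by(bird_id = .data$bird_id, year = .data$.year) |>
    dplyr::summarise(
      summering = dplyr::case_when(
        any(.data$lat >= breeding_lat) & !any(.data$lat < outside_lat) ~
          "within_breeding_range",
        all(.data$lat < outside_lat) ~ "outside_breeding_range",
        TRUE ~ "mixed"
      ),
      .groups = "drop"
    )
}
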
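#' Configuration for the synthetic track generator
#'
#' Defaults emulate the study system the pipeline targets: birds wintering on
#' Korean/Japanese coasts (35-43°N), breeding in Arctic Siberia (62.5-69°N),
#' migrating along a coastal corridor past Sakhalin and the Sea of Okhotsk.
#' Spring departures cluster in late April and autumn departures spread from
#' late August onward; travel days average 300 km; autumn has more and longer
#' stopovers than spring, so autumn migration windows are longer; migration
#' happens mostly by day with a configurable fraction of night-movement days;
#' migration legs are flown higher than residence movement, with rare
#' excursions above 1000 m. Identical seed, identical cohort.
#'
#' @param n_birds Number of birds (default 10).
#' @param years Tracked years per bird (default 1).
#' @param start_year First calendar year (default 2016).
#' @param duty_cycle_h Hours between fixes: 2, 4 or 12 (default 2).
#' @param wintering_lat_range,wintering_lon_range Wintering-site sampling
#'   box, degrees.
#' @param breeding_lat_range,breeding_lon_range Breeding-site sampling box,
#'   degrees.
#' @param nonbreeder_prob Probability that a bird summers south of 60°N
#'   instead of reaching the breeding range (default 0).
#' @param spring_departure_mean,autumn_departure_mean Month-day strings
#'   (defaults `"04-24"`, `"08-25"`).
#' @param spring_departure_sd_days,autumn_departure_sd_days SDs of the
#'   bird-level departure dates, days.
#' @param travel_speed_mean_kmday,travel_speed_sd_kmday Daily travel speed
#'   distribution, km/day (default mean 300).
#' @param spring_stopovers_mean,autumn_stopovers_mean Mean number of
#'   stopovers per migration (Poisson; defaults 1.5 and 5).
#' @param spring_stopover_days_mean,autumn_stopover_days_mean Mean stopover
#'   duration, days (defaults 2 and 5).
#' @param night_migration_prob Probability a travel day moves in the
#'   night/twilight window instead of the day window (default 0.12).
#' @param migration_alt_mean,migration_alt_sd,resident_alt_mean,resident_alt_sd
#'   Altitude model, meters: moving fixes vs residence fixes (residence draws
#'   may be negative, exercising the altitude floor).
#' @param high_alt_prob Probability a moving fix is a rare high-altitude
#'   excursion, 1000-3500 m (default 0.003).
#' @param route_noise_km Per-fix positional jitter on travel days, km sd
#'   (default 5).
#' @param individual_route_offset_km SD of the per-bird corridor offset, km;
#'   drives within- < between-individual route dissimilarity (default 30).
#' @param resident_wander_km Residence/stopover wander scale, km sd (default
#'   1.0, keeping non-travel daily path sums well below the 60 km activity
#'   threshold and making spurious >5 km two-hour displacements from jitter
#'   alone rare).
#' @param timing_shift_sd_days SD of the between-year shift of a bird's
#'   departure dates, days (default 5).
#' @param fix_failure_rate Fraction of fixes emitted as failed 0/0 attempts
#'   (default 0.01).
#' @param duplicate_rate Fraction of fixes duplicated at the same timestamp
#'   (default 0.005).
#' @param seed Integer seed (default 1).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_birds = 10, years = 1, start_year = 2016,
                             duty_cycle_h = 2,
                             wintering_lat_range = c(35, 43),
                             wintering_lon_range = c(127, 141),
                             breeding_lat_range = c(65.2, 69),
                             breeding_lon_range = c(155, 175),
                             nonbreeder_prob = 0,
                             spring_departure_mean = "04-24",
                             spring_departure_sd_days = 5,
                             autumn_departure_mean = "08-25",
                             autumn_departure_sd_days = 12,
                             travel_speed_mean_kmday = 300,
                             travel_speed_sd_kmday = 50,
                             spring_stopovers_mean = 1.5,
                             autumn_stopovers_mean = 5,
                             spring_stopover_days_mean = 2,
                             autumn_stopover_days_mean = 5,
                             night_migration_prob = 0.12,
                             migration_alt_mean = 400, migration_alt_sd = 200,
                             resident_alt_mean = 5, resident_alt_sd = 15,
                             high_alt_prob = 0.003,
                             route_noise_km = 5,
                             individual_route_offset_km = 30,
                             resident_wander_km = 1.0,
                             timing_shift_sd_days = 5,
                             fix_failure_rate = 0.01,
                             duplicate_rate = 0.005,
                             seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_birds >= 1, cfg$years >= 1, cfg$duty_cycle_h > 0,
            cfg$fix_failure_rate >= 0, cfg$fix_failure_rate <= 1,
            cfg$duplicate_rate >= 0, cfg$duplicate_rate <= 1,
            cfg$travel_speed_mean_kmday > 0)
  structure(cfg, class = "synthetic_config")
}

# Base coastal corridor (south to north) between the wintering and breeding
# boxes: East Sea coast, Sakhalin, Sea of Okhotsk, Kolyma uplands.
corridor_base <- function() {
  cbind(
    lat = c(42.0, 47.0, 51.5, 55.0, 59.5, 62.0, 64.2),
    lon = c(131.5, 138.8, 143.3, 146.0, 151.0, 156.5, 162.0)
  )
}

# Position(s) at along-route distance d (km) on the polyline given by
# waypoints (matrix lat/lon). d clamped to [0, L]. Vectorized over d.
polyline_point <- function(waypoints, d) {
  seg_len <- great_circle_km(
    waypoints[-nrow(waypoints), 1], waypoints[-nrow(waypoints), 2],
    waypoints[-1, 1], waypoints[-1, 2])
  cum <- c(0, cumsum(seg_len))
  d <- pmin(pmax(d, 0), cum[length(cum)])
  idx <- findInterval(d, cum, rightmost.closed = TRUE)
  idx <- pmin(idx, length(seg_len))
  f <- (d - cum[idx]) / seg_len[idx]
  v <- latlon_to_xyz(waypoints[, 1], waypoints[, 2])
  out <- matrix(NA_real_, length(d), 3)
  for (k in seq_along(d)) {
    out[k, ] <- slerp(v[idx[k], ], v[idx[k] + 1, ], f[k])
  }
  xyz_to_latlon(out)
}

polyline_length_km <- function(waypoints) {
  sum(great_circle_km(
    waypoints[-nrow(waypoints), 1], waypoints[-nrow(waypoints), 2],
    waypoints[-1, 1], waypoints[-1, 2]))
}

# Travel/stopover day schedule for one migration: returns a tibble of days
# with type ("travel"/"stopover"), km covered that day, and cumulative
# along-route distance at day start/end.
migration_schedule <- function(route_km, speed_mean, speed_sd,
                               stopovers_mean, stopover_days_mean) {
  speeds <- numeric(0)
  total <- 0
  while (total < route_km) {
    s <- max(100, rnorm(1, speed_mean, speed_sd))
    speeds <- c(speeds, min(s, route_km - total))
    total <- total + s
  }
  n_travel <- length(speeds)
  days <- tibble::tibble(
    type = "travel", km = speeds,
    cum_start = cumsum(speeds) - speeds, cum_end = cumsum(speeds)
  )
  n_stop <- rpois(1, stopovers_mean)
  if (n_stop > 0 && n_travel > 1) {
    at <- sort(sample(n_travel - 1, min(n_stop, n_travel - 1)))
    pieces <- list()
    prev <- 0
    for (a in at) {
      pieces <- c(pieces, list(days[(prev + 1):a, ]))
      dur <- 1 + rpois(1, max(0, stopover_days_mean - 1))
      pieces <- c(pieces, list(tibble::tibble(
        type = "stopover", km = rep(0, dur),
        cum_start = days$cum_end[a], cum_end = days$cum_end[a])))
      prev <- a
    }
    pieces <- c(pieces, list(days[(prev + 1):n_travel, ]))
    days <- dplyr::bind_rows(pieces)
  }
  days
}

# Day-level itinerary for one bird-year. Returns tibble: date, state, km,
# cum_start, cum_end, season ("spring"/"autumn" for migration days).
bird_year_itinerary <- function(cfg, year, spring_dep, autumn_dep,
                                route_len_spring, route_len_autumn) {
  spring <- migration_schedule(route_len_spring, cfg$travel_speed_mean_kmday,
                               cfg$travel_speed_sd_kmday,
                               cfg$spring_stopovers_mean,
                               cfg$spring_stopover_days_mean)
  spring$date <- spring_dep + seq_len(nrow(spring)) - 1
  spring$season <- "spring"
  spring_arr <- max(spring$date)
  if (autumn_dep <= spring_arr + 1) {
    stop("generate_cohort(): infeasible schedule (autumn departure ",
         autumn_dep, " not after spring arrival ", spring_arr, ")")
  }
  autumn <- migration_schedule(route_len_autumn, cfg$travel_speed_mean_kmday,
                               cfg$travel_speed_sd_kmday,
                               cfg$autumn_stopovers_mean,
                               cfg$autumn_stopover_days_mean)
  autumn$date <- autumn_dep + seq_len(nrow(autumn)) - 1
  autumn$season <- "autumn"
  autumn_arr <- max(autumn$date)
  if (autumn_arr >= as.Date(sprintf("%d-12-31", year))) {
    stop("generate_cohort(): infeasible schedule (autumn arrival past year end)")
  }
  dates <- seq(as.Date(sprintf("%d-01-01", year)),
               as.Date(sprintf("%d-12-31", year)), by = "day")
  it <- tibble::tibble(date = dates, state = "winter", km = 0,
                       cum_start = 0, cum_end = 0, season = NA_character_)
  mig <- dplyr::bind_rows(spring, autumn)
  i <- match(mig$date, it$date)
  it$state[i] <- mig$type
  it$km[i] <- mig$km
  it$cum_start[i] <- mig$cum_start
  it$cum_end[i] <- mig$cum_end
  it$season[i] <- mig$season
  summer_days <- it$date > spring_arr & it$date < autumn_dep
  it$state[summer_days] <- "summer"
  it
}

#' Generate a synthetic GPS tracking cohort
#'
#' Simulates each bird-year as winter residence, spring migration along a
#' bird-specific coastal corridor with scripted travel days and stopovers,
#' summer residence, autumn migration, and winter residence again, emitting
#' fixes at the configured duty cycle with positional jitter, diel-structured
#' movement, an altitude model, and injected failed (0/0) and duplicate
#' fixes. Fully reproducible from `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return A list: `fixes` (fix tibble in the layout [read_fix_table()]
#'   produces, including injected artifacts), `deployments`, and `truth`, a
#'   list of ground-truth tables: `birds` (sites, corridor offsets, labels),
#'   `daily` (per bird-day scripted state, clean distance and mean latitude),
#'   `windows` (scripted first/last day of active migration per bird, season
#'   and year, under the 60 km / 40.9-64.9°N definition), `injected`
#'   (per-bird counts of injected failed and duplicate fixes).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)

  base <- corridor_base()
  birds <- tibble::tibble(
    bird_id = sprintf("syn%02d", seq_len(cfg$n_birds)),
    winter_lat = runif(cfg$n_birds, cfg$wintering_lat_range[1], cfg$wintering_lat_range[2]),
    winter_lon = runif(cfg$n_birds, cfg$wintering_lon_range[1], cfg$wintering_lon_range[2]),
    nonbreeder = runif(cfg$n_birds) < cfg$nonbreeder_prob,
    offset_km = rnorm(cfg$n_birds, 0, cfg$individual_route_offset_km),
    spring_dep_base = rnorm(cfg$n_birds, 0, cfg$spring_departure_sd_days),
    autumn_dep_base = rnorm(cfg$n_birds, 0, cfg$autumn_departure_sd_days)
  )
  birds$summer_lat <- ifelse(
    birds$nonbreeder,
    runif(cfg$n_birds, 53, 58),
    runif(cfg$n_birds, cfg$breeding_lat_range[1], cfg$breeding_lat_range[2]))
  birds$summer_lon <- ifelse(
    birds$nonbreeder,
    base[findInterval(birds$summer_lat, base[, "lat"]), "lon"] +
      runif(cfg$n_birds, -1, 1),
    runif(cfg$n_birds, cfg$breeding_lon_range[1], cfg$breeding_lon_range[2]))

  all_fixes <- list()
  truth_daily <- list()
  truth_windows <- list()

  for (b in seq_len(cfg$n_birds)) {
    bd <- birds[b, ]
    # bird-specific corridor: lateral lon offset, clipped below the summer site
    wp <- base
    wp[, "lon"] <- wp[, "lon"] + bd$offset_km / (111 * cos(wp[, "lat"] * pi / 180))
    wp <- wp[wp[, "lat"] < bd$summer_lat, , drop = FALSE]
    route_n <- rbind(c(bd$winter_lat, bd$winter_lon), wp,
                     c(bd$summer_lat, bd$summer_lon))
    route_s <- route_n[rev(seq_len(nrow(route_n))), , drop = FALSE]
    len_n <- polyline_length_km(route_n)

    year_shift_spring <- c(0, round(rnorm(max(0, cfg$years - 1), 0, cfg$timing_shift_sd_days)))
    year_shift_autumn <- c(0, round(rnorm(max(0, cfg$years - 1), 0, cfg$timing_shift_sd_days)))

    its <- list()
    for (y in seq_len(cfg$years)) {
      yr <- cfg$start_year + y - 1
      spring_dep <- as.Date(sprintf("%d-%s", yr, cfg$spring_departure_mean)) +
        round(bd$spring_dep_base) + year_shift_spring[y]
      autumn_dep <- as.Date(sprintf("%d-%s", yr, cfg$autumn_departure_mean)) +
        round(bd$autumn_dep_base) + year_shift_autumn[y]
      it <- bird_year_itinerary(cfg, yr, spring_dep, autumn_dep, len_n, len_n)
      it$year <- yr
      its[[y]] <- it
    }
    it <- dplyr::bind_rows(its)

    # fix schedule: duty-cycle instants over the tracked span, KST clock
    t0 <- lubridate::force_tz(lubridate::as_datetime(min(it$date)), TZ_KST)
    t1 <- lubridate::force_tz(lubridate::as_datetime(max(it$date) + 1), TZ_KST) - 1
    times <- seq(from = t0, to = t1, by = cfg$duty_cycle_h * 3600)
    fix_date <- lubridate::as_date(times, tz = TZ_KST)
    hour <- lubridate::hour(lubridate::with_tz(times, TZ_KST)) +
      lubridate::minute(lubridate::with_tz(times, TZ_KST)) / 60

    di <- match(fix_date, it$date)
    state <- it$state[di]
    season <- it$season[di]
    km <- it$km[di]
    cum_start <- it$cum_start[di]
    cum_end <- it$cum_end[di]
    year_of <- it$year[di]

    # per travel day: day-window (07-19 h) or night-window (00-06 h, the
    # pre-dawn dark hours at these longitudes) movement
    travel_days <- unique(fix_date[state == "travel"])
    night_day <- setNames(runif(length(travel_days)) < cfg$night_migration_prob,
                          as.character(travel_days))
    is_night <- unname(night_day[as.character(fix_date)])
    w_start <- ifelse(is_night, 0, 7)
    w_len <- ifelse(is_night, 6, 12)
    frac <- pmin(pmax((hour - w_start) / w_len, 0), 1)

    moving <- state == "travel" & frac > 0 & frac < 1
    along <- cum_start + frac * km
    along[state != "travel"] <- NA

    # seasonal routes differ in direction; along-route distance is measured
    # from the season's own origin
    lat <- lon <- rep(NA_real_, length(times))
    trv_n <- which(state == "travel" & season == "spring")
    trv_s <- which(state == "travel" & season == "autumn")
    if (length(trv_n)) {
      p <- polyline_point(route_n, along[trv_n])
      lat[trv_n] <- p$lat; lon[trv_n] <- p$lon
    }
    if (length(trv_s)) {
      p <- polyline_point(route_s, along[trv_s])
      lat[trv_s] <- p$lat; lon[trv_s] <- p$lon
    }
    stp_n <- which(state == "stopover" & season == "spring")
    stp_s <- which(state == "stopover" & season == "autumn")
    if (length(stp_n)) {
      p <- polyline_point(route_n, cum_start[stp_n])
      lat[stp_n] <- p$lat; lon[stp_n] <- p$lon
    }
    if (length(stp_s)) {
      p <- polyline_point(route_s, cum_start[stp_s])
      lat[stp_s] <- p$lat; lon[stp_s] <- p$lon
    }
    lat[state == "winter"] <- bd$winter_lat
    lon[state == "winter"] <- bd$winter_lon
    lat[state == "summer"] <- bd$summer_lat
    lon[state == "summer"] <- bd$summer_lon

    # positional noise: route jitter on travel days, wander at residence;
    # the noise-free scripted positions are kept for the ground truth
    n <- length(times)
    lat0 <- lat; lon0 <- lon
    sd_km <- ifelse(moving, cfg$route_noise_km, cfg$resident_wander_km)
    lat <- lat + rnorm(n, 0, sd_km) / 111
    lon <- lon + rnorm(n, 0, sd_km) / (111 * cos(lat * pi / 180))

    altitude <- ifelse(
      moving,
      pmax(rnorm(n, cfg$migration_alt_mean, cfg$migration_alt_sd), 20),
      rnorm(n, cfg$resident_alt_mean, cfg$resident_alt_sd))
    high <- moving & runif(n) < cfg$high_alt_prob
    altitude[high] <- runif(sum(high), 1000, 3500)

    fixes <- tibble::tibble(
      bird_id = bd$bird_id,
      timestamp = lubridate::with_tz(times, "UTC"),
      lat = lat, lon = lon,
      altitude_m = round(altitude, 1),
      voltage_v = 4.1
    )

    # scripted (noise-free) daily truth
    step_km <- great_circle_km(lat0[-n], lon0[-n], lat0[-1], lon0[-1])
    day_km <- tapply(c(step_km, 0), fix_date, sum)
    vsum <- rowsum(latlon_to_xyz(lat0, lon0), group = as.character(fix_date))
    mlat <- xyz_to_latlon(vsum / sqrt(rowSums(vsum^2)))$lat
    daily <- tibble::tibble(
      bird_id = bd$bird_id,
      date = as.Date(names(day_km)),
      state = it$state[match(as.Date(names(day_km)), it$date)],
      year = it$year[match(as.Date(names(day_km)), it$date)],
      km_true = as.numeric(day_km),
      mean_lat_true = mlat[match(as.character(as.Date(names(day_km))),
                                 rownames(vsum))]
    )
    truth_daily[[b]] <- daily

    act <- daily |>
      dplyr::filter(.data$km_true > 60,
                    .data$mean_lat_true >= 40.9, .data$mean_lat_true <= 64.9) |>
      dplyr::mutate(md = format(.data$date, "%m-%d"),
                    season = dplyr::case_when(.data$md < "06-07" ~ "spring",
                                              .data$md > "08-31" ~ "autumn",
                                              TRUE ~ NA_character_)) |>
      dplyr::filter(!is.na(.data$season))
    if (nrow(act) > 0) {
      truth_windows[[b]] <- act |>
        dplyr::group_by(.data$bird_id, .data$season, .data$year) |>
        dplyr::summarise(first_active = min(.data$date),
                         last_active = max(.data$date),
                         n_active_days = dplyr::n(), .groups = "drop")
    }
    all_fixes[[b]] <- fixes
  }

  fixes <- dplyr::bind_rows(all_fixes)

  # inject failed (0/0) attempts, then duplicates of clean fixes
  n_all <- nrow(fixes)
  fail_idx <- which(runif(n_all) < cfg$fix_failure_rate)
  clean_idx <- setdiff(seq_len(n_all), fail_idx)
  dup_idx <- clean_idx[runif(length(clean_idx)) < cfg$duplicate_rate]
  injected <- tibble::tibble(bird_id = birds$bird_id) |>
    dplyr::left_join(
      dplyr::count(fixes[fail_idx, ], .data$bird_id, name = "n_failed"),
      by = "bird_id") |>
    dplyr::left_join(
      dplyr::count(fixes[dup_idx, ], .data$bird_id, name = "n_duplicate"),
      by = "bird_id") |>
    dplyr::mutate(dplyr::across(c("n_failed", "n_duplicate"),
                                ~ dplyr::coalesce(.x, 0L)))
  fixes$lat[fail_idx] <- 0
  fixes$lon[fail_idx] <- 0
  fixes <- dplyr::bind_rows(fixes, fixes[dup_idx, ]) |>
    dplyr::arrange(.data$bird_id, .data$timestamp)

  deployments <- tibble::tibble(
    bird_id = birds$bird_id,
    site = "custom",
    tag_model = "SYN-GPS",
    duty_cycle_h = cfg$duty_cycle_h,
    start_date = as.Date(sprintf("%d-01-01", cfg$start_year)),
    end_date = as.Date(sprintf("%d-12-31", cfg$start_year + cfg$years - 1)),
    age_class = "adult",
    sex = "unknown"
  )

  list(
    fixes = fixes,
    deployments = deployments,
    truth = list(
      birds = birds,
      daily = dplyr::bind_rows(truth_daily),
      windows = dplyr::bind_rows(truth_windows),
      injected = injected
    ),
    config = cfg
  )
}
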
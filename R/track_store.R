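#' Column preset for Movebank-style biologging CSV
#'
#' @return A named list mapping the package's canonical fix columns to
#'   Movebank column names.
#' @export
movebank_columns <- function() {
  list(
    bird_id = "individual-local-identifier",
    timestamp = "timestamp",
    lat = "location-lat",
    lon = "location-long",
    altitude_m = "height-above-msl",
    voltage_v = "tag-voltage"
  )
}

#' Read a GPS fix table
#'
#' Reads a biologging CSV (UTF-8, header row) into the package's canonical
#' fix-table layout: one row per fix with `bird_id`, `timestamp` (POSIXct,
#' UTC), `lat`, `lon`, and optional `altitude_m` and `voltage_v`. Fixes are
#' sorted by bird and time. Rows whose timestamp or coordinates cannot be
#' parsed are dropped from the returned table but reported, not silently
#' discarded: the count and row numbers are attached as the `"problems"`
#' attribute and a warning is raised.
#'
#' @param path Path to the CSV file.
#' @param column_map Named list mapping canonical names (`bird_id`,
#'   `timestamp`, `lat`, `lon`, and optionally `altitude_m`, `voltage_v`) to
#'   the file's column names. Defaults to the identity mapping; see
#'   [movebank_columns()] for the Movebank preset.
#' @param tz_offset_hours Fixed UTC offset (hours) in which the file's
#'   timestamps are expressed; they are converted to UTC on read. Default 0.
#' @return A fix tibble sorted by `bird_id`, `timestamp`.
#' @export
read_fix_table <- function(path, column_map = NULL, tz_offset_hours = 0) {
  if (!file.exists(path)) stop("read_fix_table(): file not found: ", path)
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  map <- column_map %||%
    list(bird_id = "bird_id", timestamp = "timestamp", lat = "lat", lon = "lon",
         altitude_m = "altitude_m", voltage_v = "voltage_v")
  required <- c("bird_id", "timestamp", "lat", "lon")
  for (f in required) {
    col <- map[[f]]
    if (is.null(col) || !col %in% names(raw)) {
      stop("read_fix_table(): required column missing from file: ",
           f, " (mapped to '", col %||% "<unmapped>", "')")
    }
  }
  out <- tibble::tibble(
    bird_id = raw[[map$bird_id]],
    timestamp_raw = raw[[map$timestamp]],
    lat = suppressWarnings(as.numeric(raw[[map$lat]])),
    lon = suppressWarnings(as.numeric(raw[[map$lon]]))
  )
  for (f in c("altitude_m", "voltage_v")) {
    col <- map[[f]]
    out[[f]] <- if (!is.null(col) && col %in% names(raw)) {
      suppressWarnings(as.numeric(raw[[col]]))
    } else NA_real_
  }
  ts <- suppressWarnings(lubridate::ymd_hms(out$timestamp_raw, tz = "UTC", quiet = TRUE))
  retry <- is.na(ts) & !is.na(out$timestamp_raw)
  if (any(retry)) {
    ts[retry] <- suppressWarnings(
      lubridate::parse_date_time(out$timestamp_raw[retry],
                                 orders = c("ymd HM", "dmy HMS", "dmy HM", "ymd"),
                                 tz = "UTC", quiet = TRUE))
  }
  out$timestamp <- ts - tz_offset_hours * 3600

  bad <- is.na(out$timestamp) | is.na(out$lat) | is.na(out$lon) | is.na(out$bird_id)
  problems <- tibble::tibble(
    row = which(bad),
    reason = dplyr::case_when(
      is.na(out$timestamp[bad]) ~ "unparseable timestamp",
      TRUE ~ "unparseable coordinates"
    )
  )
  if (nrow(problems) > 0) {
    warning("read_fix_table(): ", nrow(problems),
            " malformed row(s) dropped (see attr(, 'problems'))")
  }
  res <- out[!bad, c("bird_id", "timestamp", "lat", "lon", "altitude_m", "voltage_v")] |>
    dplyr::arrange(.data$bird_id, .data$timestamp)
  attr(res, "problems") <- problems
  res
}

#' Remove failed and duplicate fixes
#'
#' Fix-level filtering: drops failed location attempts (latitude and longitude
#' both exactly 0) and duplicate fixes (same bird, same timestamp; the first
#' is kept). Identical coordinates at different timestamps are retained -- a
#' roosting bird legitimately repeats its position. The operation is
#' idempotent.
#'
#' @param fixes A fix tibble.
#' @return The filtered fix tibble, with a per-bird removal report attached as
#'   the `"removal_report"` attribute (see [removal_report()]).
#' @export
filter_fixes <- function(fixes) {
  fixes <- dplyr::arrange(fixes, .data$bird_id, .data$timestamp)
  failed <- fixes$lat == 0 & fixes$lon == 0
  dup <- duplicated(fixes[, c("bird_id", "timestamp")]) & !failed
  # a failed fix sharing a timestamp is counted as failed, not duplicate
  report <- fixes |>
    dplyr::mutate(.failed = failed, .dup = dup) |>
    dplyr::group_by(.data$bird_id) |>
    dplyr::summarise(
      n_in = dplyr::n(),
      n_failed = sum(.data$.failed),
      n_duplicate = sum(.data$.dup),
      n_kept = .data$n_in - .data$n_failed - .data$n_duplicate,
      .groups = "drop"
    )
  out <- fixes[!failed & !dup, , drop = FALSE]
  attr(out, "removal_report") <- report
  out
}

#' @rdname filter_fixes
#' @param x A fix tibble returned by [filter_fixes()].
#' @return For `removal_report()`: the per-bird tibble of removal counts by
#'   reason (`n_in`, `n_failed`, `n_duplicate`, `n_kept`).
#' @export
removal_report <- function(x) {
  attr(x, "removal_report")
}

#' Monitoring-duration inclusion filter
#'
#' Drops birds monitored for fewer than `min_days` days. The monitored span is
#' the difference between the last and first fix dates on the UTC+9 calendar
#' (the convention of the deployment summaries: a track from 25 Feb to 26 Oct
#' of the same year spans 243 days).
#'
#' @param fixes A filtered fix tibble.
#' @param min_days Minimum monitored span in days (default 100).
#' @param tz Time zone defining calendar days (default UTC+9).
#' @return The fix tibble restricted to included birds; the excluded birds and
#'   their spans are attached as the `"excluded"` attribute (see
#'   [excluded_birds()]).
#' @export
apply_inclusion_filter <- function(fixes, min_days = 100, tz = TZ_KST) {
  spans <- fixes |>
    dplyr::group_by(.data$bird_id) |>
    dplyr::summarise(
      n_days = as.integer(max(lubridate::as_date(.data$timestamp, tz = tz)) -
                            min(lubridate::as_date(.data$timestamp, tz = tz))),
      .groups = "drop"
    )
  excl <- dplyr::filter(spans, .data$n_days < min_days)
  out <- dplyr::filter(fixes, !.data$bird_id %in% excl$bird_id)
  attr(out, "excluded") <- excl
  out
}

#' @rdname apply_inclusion_filter
#' @param x A fix tibble returned by [apply_inclusion_filter()].
#' @export
excluded_birds <- function(x) {
  attr(x, "excluded")
}

#' Infer the fate of each tracked bird
#'
#' End-of-monitoring classification: `dead_or_tag_lost` when the terminal
#' window is stationary (all fixes in the final `stationary_days` days within
#' `stationary_radius_km` of each other), `technical_failure` when the number
#' of collected positions is at or below `completeness_max` of the expected
#' number (from the duty cycle) and/or the last recorded voltage is at or
#' below `voltage_min`, `alive_at_censoring` when still transmitting at
#' `study_end`, otherwise `unknown`. Stationarity takes precedence; a missing
#' voltage column skips the voltage criterion and notes it in the evidence.
#'
#' @param fixes A filtered fix tibble.
#' @param deployments Deployment tibble with `bird_id` and `duty_cycle_h`.
#' @param study_end Optional date: birds with a fix on or after it are
#'   `alive_at_censoring` (unless stationary).
#' @param stationary_days,stationary_radius_km Terminal stationarity window
#'   (default: 5 days, 0.5 km).
#' @param completeness_max,voltage_min Technical-failure thresholds (default
#'   0.80 and 3.9 V).
#' @return A tibble per bird: `fate` and `evidence` (semicolon-joined list of
#'   triggered criteria).
#' @export
classify_fate <- function(fixes, deployments, study_end = NULL,
                          stationary_days = 5, stationary_radius_km = 0.5,
                          completeness_max = 0.80, voltage_min = 3.9) {
  fixes |>
    dplyr::group_by(.data$bird_id) |>
    dplyr::group_modify(function(df, key) {
      dep <- deployments[deployments$bird_id == key$bird_id, ]
      evidence <- character(0)

      t_end <- max(df$timestamp)
      term <- df[df$timestamp >= t_end - stationary_days * 86400, ]
      ctr <- spherical_mean(term$lat, term$lon)
      stationary <- nrow(term) >= 2 &&
        max(great_circle_km(term$lat, term$lon, ctr$lat, ctr$lon)) <=
          stationary_radius_km
      if (stationary) evidence <- c(evidence, "terminal window stationary")

      completeness <- NA_real_
      if (nrow(dep) == 1 && is.finite(dep$duty_cycle_h)) {
        span_h <- as.numeric(difftime(t_end, min(df$timestamp), units = "hours"))
        expected <- span_h / dep$duty_cycle_h + 1
        completeness <- nrow(df) / expected
        if (completeness <= completeness_max) {
          evidence <- c(evidence, sprintf("completeness %.0f%% <= %.0f%%",
                                          100 * completeness, 100 * completeness_max))
        }
      }
      low_volt <- FALSE
      if ("voltage_v" %in% names(df) && any(is.finite(df$voltage_v))) {
        last_v <- df$voltage_v[max(which(is.finite(df$voltage_v)))]
        low_volt <- last_v <= voltage_min
        if (low_volt) evidence <- c(evidence, sprintf("last voltage %.2f V", last_v))
      } else {
        evidence <- c(evidence, "voltage unavailable, criterion skipped")
      }
      censored <- !is.null(study_end) &&
        lubridate::as_date(t_end, tz = TZ_KST) >= lubridate::as_date(study_end)

      fate <- if (stationary) {
        "dead_or_tag_lost"
      } else if ((is.finite(completeness) && completeness <= completeness_max) || low_volt) {
        "technical_failure"
      } else if (censored) {
        "alive_at_censoring"
      } else {
        "unknown"
      }
      tibble::tibble(fate = fate, evidence = paste(evidence, collapse = "; "))
    }) |>
    dplyr::ungroup()
}

#' Per-bird deployment summary
#'
#' One row per bird with the quantities of a deployment summary table:
#' monitored span in days (UTC+9 calendar, last minus first date), number of
#' fixes, total track length (sum of consecutive-fix great-circle distances),
#' mean distance travelled per day (total track over monitored days), and the
#' longest great-circle distance between any summer-period fix (7 Jun-31 Aug)
#' and any winter-period fix (18 Dec-12 Apr).
#'
#' @param fixes A filtered fix tibble.
#' @param tz Time zone defining calendar days (default UTC+9).
#' @return A tibble: `bird_id`, `start_date`, `end_date`, `n_days`, `n_fixes`,
#'   `total_km`, `mean_km_per_day`, `longest_gc_km`.
#' @export
track_summary <- function(fixes, tz = TZ_KST) {
  lens <- path_length_km(fixes)
  fixes |>
    dplyr::group_by(.data$bird_id) |>
    dplyr::group_modify(function(df, key) {
      dates <- lubridate::as_date(df$timestamp, tz = tz)
      n_days <- as.integer(max(dates) - min(dates))
      season <- assign_season(dates)
      longest <- longest_seasonal_gc(df, season)
      tibble::tibble(
        start_date = min(dates), end_date = max(dates),
        n_days = n_days, n_fixes = nrow(df),
        longest_gc_km = longest
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::left_join(lens, by = "bird_id") |>
    dplyr::mutate(
      mean_km_per_day = ifelse(.data$n_days > 0, .data$total_km / .data$n_days, NA_real_)
    ) |>
    dplyr::select("bird_id", "start_date", "end_date", "n_days", "n_fixes",
                  "total_km", "mean_km_per_day", "longest_gc_km")
}

# Max great-circle distance between any summer fix and any winter fix,
# exhaustive pairwise scan in chunks to bound memory.
longest_seasonal_gc <- function(df, season) {
  su <- df[season == "summer", ]
  wi <- df[season == "winter", ]
  if (nrow(su) == 0 || nrow(wi) == 0) return(NA_real_)
  best <- 0
  chunk <- max(1L, floor(2e6 / nrow(wi)))
  for (i in seq(1, nrow(su), by = chunk)) {
    j <- min(i + chunk - 1, nrow(su))
    block <- outer(seq(i, j), seq_len(nrow(wi)), function(a, b) {
      great_circle_km(su$lat[a], su$lon[a], wi$lat[b], wi$lon[b])
    })
    best <- max(best, block)
  }
  best
}

# Round half away from zero (printed-table convention: 3357.75 -> 3358).
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Cohort summary statistics
#'
#' Aggregates per-bird summary rows ([track_summary()] output, or a compatible
#' table with columns `n_days`, `n_fixes`, `total_km`, `longest_gc_km`) into
#' cohort totals and means. Integer-reported per-bird means use half-away-from-
#' zero rounding, the convention of printed deployment tables. The grand mean
#' distance per day is total kilometers over total days (not the mean of the
#' per-bird means).
#'
#' @param summaries A per-bird summary tibble.
#' @return A one-row tibble of cohort statistics. With a single bird the
#'   standard deviation of `longest_gc_km` is `NA`.
#' @export
cohort_summary <- function(summaries) {
  if (nrow(summaries) == 0) stop("cohort_summary(): empty input")
  tibble::tibble(
    n_birds = nrow(summaries),
    total_days = sum(summaries$n_days),
    total_fixes = sum(summaries$n_fixes),
    total_km = sum(summaries$total_km),
    mean_days_per_bird = round_half_away(mean(summaries$n_days)),
    mean_fixes_per_bird = round_half_away(mean(summaries$n_fixes)),
    mean_km_per_bird = round_half_away(mean(summaries$total_km)),
    grand_mean_km_per_day = sum(summaries$total_km) / sum(summaries$n_days),
    min_fixes = min(summaries$n_fixes),
    max_fixes = max(summaries$n_fixes),
    mean_longest_gc_km = mean(summaries$longest_gc_km, na.rm = TRUE),
    sd_longest_gc_km = if (nrow(summaries) > 1) {
      sd(summaries$longest_gc_km, na.rm = TRUE)
    } else NA_real_,
    min_longest_gc_km = min(summaries$longest_gc_km, na.rm = TRUE),
    max_longest_gc_km = max(summaries$longest_gc_km, na.rm = TRUE)
  )
}

#' Analysis subsamples
#'
#' Deterministic track subsets used by the downstream analyses:
#' \describe{
#'   \item{A}{adult birds that summered within the breeding range, i.e.
#'     reached at least `breeding_lat` (64.9°N) during the summer band.}
#'   \item{B}{birds whose logger had a 2 h duty cycle.}
#'   \item{C}{birds monitored over a full spring + autumn migration cycle of
#'     the same year: at least one fix in the pre-spring winter period
#'     (before 13 Apr) and one after the autumn band (on/after 18 Dec) of the
#'     same year. For birds with several qualifying years only the first year
#'     of data (that calendar year) is retained.}
#' }
#'
#' @param fixes A filtered fix tibble.
#' @param deployments Deployment tibble (`bird_id`, `duty_cycle_h`,
#'   `age_class`).
#' @param rule One of `"A"`, `"B"`, `"C"`.
#' @param breeding_lat Southern limit of the breeding range used by rule A
#'   (default 64.9).
#' @param tz Time zone for calendar dates (default UTC+9).
#' @return The fix tibble restricted to the subsample (possibly empty), with
#'   the selected bird ids in the `"birds"` attribute.
#' @export
select_subsample <- function(fixes, deployments, rule,
                             breeding_lat = 64.9, tz = TZ_KST) {
  rule <- as.character(rule)
  if (!rule %in% c("A", "B", "C")) stop("select_subsample(): unknown rule: ", rule)
  out <- switch(rule,
    A = {
      season <- assign_season(lubridate::as_date(fixes$timestamp, tz = tz))
      reach <- fixes |>
        dplyr::mutate(.season = season) |>
        dplyr::group_by(.data$bird_id) |>
        dplyr::summarise(
          within = any(.data$.season == "summer" & .data$lat >= breeding_lat),
          .groups = "drop")
      adults <- deployments$bird_id[deployments$age_class == "adult"]
      keep <- reach$bird_id[reach$within & reach$bird_id %in% adults]
      dplyr::filter(fixes, .data$bird_id %in% keep)
    },
    B = {
      keep <- deployments$bird_id[deployments$duty_cycle_h == 2]
      dplyr::filter(fixes, .data$bird_id %in% keep)
    },
    C = {
      dates <- lubridate::as_date(fixes$timestamp, tz = tz)
      yr <- lubridate::year(dates)
      md <- format(dates, "%m-%d")
      cand <- tibble::tibble(bird_id = fixes$bird_id, yr = yr, md = md) |>
        dplyr::group_by(.data$bird_id, .data$yr) |>
        dplyr::summarise(
          pre = any(.data$md < "04-13"),
          post = any(.data$md >= "12-18"),
          .groups = "drop") |>
        dplyr::filter(.data$pre & .data$post) |>
        dplyr::group_by(.data$bird_id) |>
        dplyr::summarise(year = min(.data$yr), .groups = "drop")
      fixes |>
        dplyr::mutate(.yr = yr) |>
        dplyr::inner_join(cand, by = "bird_id") |>
        dplyr::filter(.data$.yr == .data$year) |>
        dplyr::select(-".yr", -"year")
    }
  )
  attr(out, "birds") <- unique(out$bird_id)
  out
}

#' Reference cohort deployment table
#'
#' The packaged deployment summary for a 28-bird GPS tracking cohort of Vega
#' gulls (three trapping sites, 2015-2019), used as the arithmetic validation
#' fixture for [cohort_summary()]: per bird the monitored span, filtered fix
#' count, duty cycle (fixes per day), total track length, mean distance per
#' day and longest summer-winter great-circle distance, as printed in the
#' source summary table.
#'
#' @return A 28-row tibble.
#' @export
vega_cohort_table <- function() {
  path <- system.file("extdata", "vega_cohort_summary.csv", package = "vegamove",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    bird_id = "c", site = "c", age_class = "c", sex = "c",
                    tag_model = "c", start_date = "D", end_date = "D",
                    n_days = "i", n_fixes = "i", fixes_per_day = "c",
                    total_km = "d", mean_km_per_day = "d",
                    longest_gc_km = "d", summering = "c"
                  ))
}
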
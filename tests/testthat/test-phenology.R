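test_that("season bands partition the year at the stated boundaries", {
  expect_equal(assign_season(as.Date("2017-01-15")), "winter")
  expect_equal(assign_season(as.Date("2017-04-12")), "winter")
  expect_equal(assign_season(as.Date("2017-04-13")), "spring")
  expect_equal(assign_season(as.Date("2017-06-06")), "spring")
  expect_equal(assign_season(as.Date("2017-06-07")), "summer")
  expect_equal(assign_season(as.Date("2017-08-31")), "summer")
  expect_equal(assign_season(as.Date("2017-09-01")), "autumn")
  expect_equal(assign_season(as.Date("2017-12-17")), "autumn")
  expect_equal(assign_season(as.Date("2017-12-18")), "winter")
  # every day of a full year gets exactly one label
  yr <- seq(as.Date("2017-01-01"), as.Date("2017-12-31"), by = "day")
  expect_true(all(assign_season(yr) %in% c("winter", "spring", "summer", "autumn")))
})

test_that("daily series assigns each step to its start date", {
  # a 70 km leg starting at 23:00 KST belongs entirely to the start date
  t0 <- kst("2017-05-01 23:00")
  fx <- make_fixes("b", c(t0, t0 + 2 * 3600), c(50, 50.63), c(140, 140))
  d <- daily_series(fx)
  expect_equal(as.character(d$date), c("2017-05-01", "2017-05-02"))
  expect_equal(d$distance_km[1], great_circle_km(50, 140, 50.63, 140),
               tolerance = 1e-9)
  expect_equal(d$distance_km[2], 0)

  # stationary day
  still <- make_fixes("b", kst("2017-05-01 00:00") + (0:5) * 7200,
                      rep(45, 6), rep(135, 6))
  expect_equal(daily_series(still)$distance_km, 0)
})

test_that("daily series matches generator ground truth exactly without noise", {
  syn <- generate_cohort(synthetic_config(
    n_birds = 2, years = 1, duty_cycle_h = 2, seed = 23,
    route_noise_km = 0, resident_wander_km = 0,
    fix_failure_rate = 0, duplicate_rate = 0))
  d <- daily_series(syn$fixes)
  cmp <- dplyr::inner_join(d, syn$truth$daily, by = c("bird_id", "date"))
  expect_equal(nrow(cmp), nrow(syn$truth$daily))
  expect_equal(cmp$distance_km, cmp$km_true, tolerance = 1e-9)
  expect_equal(cmp$mean_lat, cmp$mean_lat_true, tolerance = 1e-9)
})

test_that("active-day classification applies both thresholds strictly", {
  days <- tibble::tibble(
    bird_id = "b", date = as.Date("2017-05-01") + 0:2, n_fixes = 12,
    distance_km = c(70, 70, 60), mean_lat = c(50, 38, 50), mean_lon = 140
  )
  out <- classify_active_days(days)
  expect_equal(out$active, c(TRUE, FALSE, FALSE))
})

test_that("individual windows compute span, counts and proportions", {
  base <- tibble::tibble(
    bird_id = "b", n_fixes = 12, mean_lon = 140, mean_lat = 50
  )
  # single active day
  one <- dplyr::mutate(base, date = as.Date("2017-05-10"), distance_km = 100) |>
    classify_active_days()
  w1 <- individual_windows(one)
  expect_equal(w1$duration_days, 1L)
  expect_equal(w1$prop_active, 1)
  expect_equal(w1$season, "spring")

  # active May 1 and May 20 with 5 active days total: duration 20, prop 0.25
  dates <- as.Date(c("2017-05-01", "2017-05-05", "2017-05-08", "2017-05-12",
                     "2017-05-20"))
  five <- tidyr::crossing(base, date = dates) |>
    dplyr::mutate(distance_km = 100) |>
    classify_active_days()
  w5 <- individual_windows(five)
  expect_equal(w5$duration_days, 20L)
  expect_equal(w5$n_active_days, 5L)
  expect_equal(w5$prop_active, 0.25)
})

test_that("population window is the union span of individual windows", {
  mk <- function(bird, dates) {
    tibble::tibble(bird_id = bird, date = as.Date(dates), n_fixes = 12,
                   distance_km = 100, mean_lat = 50, mean_lon = 140) |>
      classify_active_days()
  }
  solo <- mk("a", c("2017-05-02", "2017-05-10"))
  pw1 <- population_window(solo, "spring", 2017)
  iw1 <- individual_windows(solo)
  expect_equal(pw1$window$first_active, iw1$first_active)
  expect_equal(pw1$window$last_active, iw1$last_active)

  both <- dplyr::bind_rows(mk("a", c("2017-05-02", "2017-05-05")),
                           mk("b", c("2017-05-15", "2017-05-20")))
  pw2 <- population_window(both, "spring", 2017)
  expect_equal(as.character(pw2$window$first_active), "2017-05-02")
  expect_equal(as.character(pw2$window$last_active), "2017-05-20")
  expect_equal(pw2$window$duration_days, 19L)
  # per-bird proportions within the population window
  pb <- pw2$per_bird
  expect_equal(pb$prop_active, c(2 / 19, 2 / 19))
})

test_that("individual windows lie inside the population window on synthetic cohorts", {
  syn <- generate_cohort(synthetic_config(n_birds = 6, years = 1,
                                          duty_cycle_h = 12, seed = 29))
  d <- daily_series(filter_fixes(syn$fixes)) |> classify_active_days()
  iw <- individual_windows(d)
  expect_true(all(iw$n_active_days <= iw$duration_days))
  for (s in unique(iw$season)) {
    pw <- population_window(d, s, 2016)
    sub <- iw[iw$season == s, ]
    expect_true(all(sub$first_active >= pw$window$first_active))
    expect_true(all(sub$last_active <= pw$window$last_active))
    expect_equal(min(sub$first_active), pw$window$first_active)
    expect_equal(max(sub$last_active), pw$window$last_active)
  }
})

test_that("route fraction on active days follows its definition", {
  base <- tibble::tibble(bird_id = "b", n_fixes = 12, mean_lat = 50,
                         mean_lon = 140)
  # 10 active days at 300 km; 10 slow 30-km days all inside the window
  # (active days bracket the span so every slow day is counted)
  days <- tidyr::crossing(base, date = as.Date("2017-05-01") + 0:19) |>
    dplyr::mutate(distance_km = c(rep(300, 9), rep(30, 10), 300)) |>
    classify_active_days()
  w <- individual_windows(days)
  rf <- route_fraction_on_active_days(days, w)
  expect_equal(rf$route_fraction_active, 3000 / 3300, tolerance = 1e-9)

  # all movement on active days: fraction 1
  all_act <- tidyr::crossing(base, date = as.Date("2017-05-01") + 0:4) |>
    dplyr::mutate(distance_km = 100) |>
    classify_active_days()
  rf2 <- route_fraction_on_active_days(all_act, individual_windows(all_act))
  expect_equal(rf2$route_fraction_active, 1)
})

test_that("summering class separates breeding-range and southern birds", {
  mk <- function(bird, lats) {
    make_fixes(bird, kst("2017-07-01") + seq_along(lats) * 86400,
               lats, rep(160, length(lats)))
  }
  s <- summering_class(dplyr::bind_rows(
    mk("within", c(68, 68.5, 67)),
    mk("outside", c(52, 53, 51)),
    mk("mixed", c(55, 66, 67))
  ))
  expect_equal(s$summering[s$bird_id == "within"], "within_breeding_range")
  expect_equal(s$summering[s$bird_id == "outside"], "outside_breeding_range")
  expect_equal(s$summering[s$bird_id == "mixed"], "mixed")

  # no summer fixes at all: bird absent from the classification
  none <- summering_class(mk("w", 68)[0, ])
  expect_equal(nrow(none), 0)
})

test_that("longer scripted stopovers lengthen recovered migration windows", {
  w_for <- function(stop_days) {
    syn <- generate_cohort(synthetic_config(
      n_birds = 5, years = 1, duty_cycle_h = 12, seed = 37,
      autumn_stopovers_mean = 4, autumn_stopover_days_mean = stop_days))
    d <- daily_series(filter_fixes(syn$fixes)) |> classify_active_days()
    individual_windows(d) |> dplyr::filter(season == "autumn")
  }
  short <- w_for(1)
  long <- w_for(8)
  expect_gt(mean(long$duration_days), mean(short$duration_days))
})

test_that("spring migration is denser than autumn under the default scenario", {
  syn <- generate_cohort(synthetic_config(n_birds = 8, years = 1,
                                          duty_cycle_h = 12, seed = 43))
  d <- daily_series(filter_fixes(syn$fixes)) |> classify_active_days()
  iw <- individual_windows(d)
  sp <- iw$prop_active[iw$season == "spring"]
  au <- iw$prop_active[iw$season == "autumn"]
  expect_gt(mean(sp), mean(au))
})
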
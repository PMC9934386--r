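write_toy_csv <- function(df, path = tempfile(fileext = ".csv")) {
  readr::write_csv(df, path)
  path
}

test_that("read_fix_table reads, sorts and partitions by bird", {
  toy <- tibble::tibble(
    bird_id = "g1",
    timestamp = c("2017-05-01 00:00:00", "2017-05-01 02:00:00",
                  "2017-05-01 04:00:00"),
    lat = c(40, 40.5, 41), lon = c(130, 130.2, 130.4)
  )
  fx <- read_fix_table(write_toy_csv(toy))
  expect_equal(nrow(fx), 3)
  expect_equal(unique(fx$bird_id), "g1")

  # out-of-order rows come back time-sorted
  fx2 <- read_fix_table(write_toy_csv(toy[c(3, 1, 2), ]))
  expect_equal(fx2$lat, c(40, 40.5, 41))

  # two interleaved birds: brute-force partition of the same file
  two <- dplyr::bind_rows(toy, dplyr::mutate(toy, bird_id = "g2", lat = lat + 5))
  two <- two[c(1, 4, 2, 5, 3, 6), ]
  fx3 <- read_fix_table(write_toy_csv(two))
  manual <- split(two, two$bird_id)
  for (b in names(manual)) {
    got <- fx3[fx3$bird_id == b, ]
    want <- manual[[b]][order(manual[[b]]$timestamp), ]
    expect_equal(got$lat, want$lat)
    expect_true(all(diff(got$timestamp) > 0))
  }
})

test_that("read_fix_table reports malformed rows and missing columns", {
  bad <- tibble::tibble(
    bird_id = "g1",
    timestamp = c("2017-05-01 00:00:00", "not-a-time", "2017-05-01 04:00:00"),
    lat = c(40, 41, 42), lon = c(130, 131, 132)
  )
  expect_warning(fx <- read_fix_table(write_toy_csv(bad)), "malformed")
  expect_equal(nrow(fx), 2)
  expect_equal(nrow(attr(fx, "problems")), 1)
  expect_match(attr(fx, "problems")$reason, "timestamp")

  noid <- dplyr::select(bad, -"bird_id")
  expect_error(read_fix_table(write_toy_csv(noid)), "required column")
  expect_error(read_fix_table(tempfile()), "not found")
})

test_that("read_fix_table applies a fixed UTC offset and a column map", {
  toy <- tibble::tibble(
    id = "g1", ts = "2017-05-01 09:00:00", y = 40, x = 130
  )
  fx <- read_fix_table(write_toy_csv(toy),
                       column_map = list(bird_id = "id", timestamp = "ts",
                                         lat = "y", lon = "x"),
                       tz_offset_hours = 9)
  expect_equal(fx$timestamp, as.POSIXct("2017-05-01 00:00:00", tz = "UTC"))
})

test_that("filter_fixes removes failed and duplicate fixes with exact counts", {
  t0 <- kst("2017-05-01 00:00")
  fx <- make_fixes("g1", t0 + c(0, 2, 4, 6, 8) * 3600,
                   c(40, 0, 41, 41.5, 42), c(130, 0, 131, 131.3, 131.6))
  out <- filter_fixes(fx)
  rep1 <- removal_report(out)
  expect_equal(nrow(out), 4)
  expect_equal(rep1$n_failed, 1)
  expect_equal(rep1$n_duplicate, 0)

  # duplicate timestamps: first kept
  dup <- dplyr::bind_rows(fx[3, ], dplyr::mutate(fx[3, ], lat = 99))
  out2 <- filter_fixes(dplyr::bind_rows(fx[1:2, ], dup))
  expect_equal(removal_report(out2)$n_duplicate, 1)
  expect_true(41 %in% out2$lat && !99 %in% out2$lat)

  # identical coordinates at different timestamps are retained
  roost <- make_fixes("g1", t0 + c(0, 2) * 3600, c(40, 40), c(130, 130))
  expect_equal(nrow(filter_fixes(roost)), 2)
})

test_that("filter_fixes is idempotent and conserves counts", {
  set.seed(61)
  syn <- generate_cohort(synthetic_config(n_birds = 2, years = 1,
                                          duty_cycle_h = 12, seed = 13))
  once <- filter_fixes(syn$fixes)
  twice <- filter_fixes(once)
  strip <- function(x) {
    attr(x, "removal_report") <- NULL
    as.data.frame(x)
  }
  expect_equal(strip(twice), strip(once))
  r2 <- removal_report(twice)
  expect_true(all(r2$n_failed == 0) && all(r2$n_duplicate == 0))

  r1 <- removal_report(once)
  expect_equal(r1$n_kept + r1$n_failed + r1$n_duplicate, r1$n_in)
  # removal counts equal the generator's injected counts exactly
  cmp <- dplyr::inner_join(r1, syn$truth$injected, by = "bird_id")
  expect_equal(cmp$n_failed.x, cmp$n_failed.y)
  expect_equal(cmp$n_duplicate.x, cmp$n_duplicate.y)
})

test_that("inclusion filter uses the monitored-span boundary", {
  t0 <- kst("2017-01-01 12:00")
  short <- make_fixes("s", t0 + c(0, 99) * 86400, c(40, 41), c(130, 131))
  long <- make_fixes("l", t0 + c(0, 100) * 86400, c(40, 41), c(130, 131))
  out <- apply_inclusion_filter(dplyr::bind_rows(short, long), min_days = 100)
  expect_equal(unique(out$bird_id), "l")
  expect_equal(excluded_birds(out)$bird_id, "s")
  expect_equal(excluded_birds(out)$n_days, 99)
})

test_that("fate classification applies the decision criteria in order", {
  t0 <- kst("2017-01-01 00:00")
  dep <- tibble::tibble(bird_id = c("dead", "fail", "ok"), duty_cycle_h = 2)

  # stationary terminal window: 10 fixes within 100 m over the last 5 days
  moving <- make_fixes("dead", t0 + (0:19) * 2 * 3600,
                       seq(40, 42, length.out = 20), rep(130, 20))
  stat <- make_fixes("dead", max(moving$timestamp) + (1:10) * 12 * 3600,
                     42 + runif(10, 0, 0.0009), rep(130, 10))
  f1 <- classify_fate(dplyr::bind_rows(moving, stat), dep)
  expect_equal(f1$fate, "dead_or_tag_lost")

  # 70% of expected fixes collected: technical failure
  times <- t0 + seq(0, 99) * 2 * 3600
  keep <- sort(sample(100, 70))
  sparse <- make_fixes("fail", times[keep], 40 + keep / 50, rep(130, 70),
                       voltage_v = 4.1)
  f2 <- classify_fate(sparse, dep)
  expect_equal(f2$fate, "technical_failure")

  # moving, complete, healthy voltage: unknown
  good <- make_fixes("ok", times, 40 + (1:100) / 50, rep(130, 100),
                     voltage_v = 4.1)
  f3 <- classify_fate(good, dep)
  expect_equal(f3$fate, "unknown")

  # missing voltage noted in evidence, criterion skipped
  f4 <- classify_fate(dplyr::mutate(good, voltage_v = NA_real_), dep)
  expect_match(f4$evidence, "voltage unavailable")
  expect_equal(f4$fate, "unknown")
})

test_that("track summaries handle degenerate tracks", {
  two_same <- make_fixes("b", kst("2017-06-10") + c(0, 3600),
                         c(68, 68), c(170, 170))
  s <- track_summary(two_same)
  expect_equal(s$total_km, 0)
  expect_equal(s$n_fixes, 2)
  expect_true(is.na(s$longest_gc_km))  # no winter fixes

  expect_error(cohort_summary(s[0, ]), "empty")
  one <- cohort_summary(tibble::tibble(bird_id = "b", n_days = 100,
                                       n_fixes = 50, total_km = 1000,
                                       longest_gc_km = 900))
  expect_true(is.na(one$sd_longest_gc_km))
  expect_equal(one$grand_mean_km_per_day, 10)
})

test_that("the packaged cohort table reproduces its own printed arithmetic", {
  tab <- vega_cohort_table()
  expect_equal(nrow(tab), 28)
  # every printed mean-distance cell equals total km / days at 1 decimal
  expect_equal(round(tab$total_km / tab$n_days, 1), tab$mean_km_per_day)
  # printed spans equal the date differences
  expect_equal(as.integer(tab$end_date - tab$start_date), tab$n_days)
})

test_that("subsample rules select deterministically", {
  syn <- generate_cohort(synthetic_config(n_birds = 8, years = 1,
                                          duty_cycle_h = 12, seed = 17,
                                          nonbreeder_prob = 0.4))
  fx <- filter_fixes(syn$fixes)
  # rule A drops exactly the birds never reaching 64.9N in summer
  a <- select_subsample(fx, syn$deployments, "A")
  truth_nb <- syn$truth$birds$bird_id[syn$truth$birds$nonbreeder]
  expect_setequal(attr(a, "birds"),
                  setdiff(syn$deployments$bird_id, truth_nb))

  # rule B: all loggers are 12 h, so the 2 h subsample is empty
  b <- select_subsample(fx, syn$deployments, "B")
  expect_equal(nrow(b), 0)

  expect_error(select_subsample(fx, syn$deployments, "Z"), "unknown rule")
})

test_that("rule C keeps only the first full-cycle year of multi-year birds", {
  syn <- generate_cohort(synthetic_config(n_birds = 2, years = 2,
                                          duty_cycle_h = 12, seed = 19))
  fx <- filter_fixes(syn$fixes)
  cc <- select_subsample(fx, syn$deployments, "C")
  yrs <- unique(lubridate::year(lubridate::as_date(cc$timestamp,
                                                   tz = "Etc/GMT-9")))
  expect_equal(yrs, 2016)
  expect_setequal(unique(cc$bird_id), syn$deployments$bird_id)
})
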
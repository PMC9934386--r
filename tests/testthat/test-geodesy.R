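test_that("great-circle distance matches an independent haversine oracle", {
  expect_equal(great_circle_km(40, 130, 40, 130), 0)
  # antipodal points on one meridian: half the Earth's circumference
  expect_equal(great_circle_km(0, 0, 0, 180), pi * 6371.0088, tolerance = 1e-6)
  # the two study sites
  d <- great_circle_km(68.833, 170.500, 37.390, 129.240)
  expect_lt(abs(d - haversine_oracle(68.833, 170.500, 37.390, 129.240)), 0.1)

  set.seed(101)
  lat1 <- runif(300, -85, 85); lon1 <- runif(300, -180, 180)
  lat2 <- runif(300, -85, 85); lon2 <- runif(300, -180, 180)
  expect_lt(max(abs(great_circle_km(lat1, lon1, lat2, lon2) -
                      haversine_oracle(lat1, lon1, lat2, lon2))), 0.1)
})

test_that("great-circle distance satisfies the triangle inequality", {
  set.seed(7)
  for (k in 1:50) {
    lat <- runif(3, -85, 85); lon <- runif(3, -180, 180)
    ab <- great_circle_km(lat[1], lon[1], lat[2], lon[2])
    bc <- great_circle_km(lat[2], lon[2], lat[3], lon[3])
    ac <- great_circle_km(lat[1], lon[1], lat[3], lon[3])
    expect_lte(ac, ab + bc + 1e-9)
  }
})

test_that("spherical mean handles symmetry and the antimeridian", {
  one <- spherical_mean(51.3, 143.2)
  expect_equal(c(one$lat, one$lon), c(51.3, 143.2), tolerance = 1e-9)

  # two points symmetric about a meridian average onto it
  sym <- spherical_mean(c(45, 45), c(139, 141))
  expect_equal(sym$lon, 140, tolerance = 1e-9)

  # a cluster straddling the antimeridian averages near 180, not 0
  am <- spherical_mean(c(60, 61, 60.5), c(179, -179, 179.5))
  expect_gt(abs(am$lon), 179)

  # agrees with a brute-force minimizer of summed squared great-circle
  # distance on a random cluster
  set.seed(11)
  lat <- runif(8, 50, 55); lon <- runif(8, 150, 160)
  sm <- spherical_mean(lat, lon)
  obj <- function(p) sum(great_circle_km(p[1], p[2], lat, lon)^2)
  opt <- optim(c(52, 155), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14))
  expect_lt(great_circle_km(sm$lat, sm$lon, opt$par[1], opt$par[2]), 0.5)

  expect_error(spherical_mean(c(10, -10), c(0, 180)), "zero resultant")
})

test_that("path length sums consecutive great-circle steps", {
  trk <- make_fixes("b1", kst("2017-01-01") + (0:2) * 3600, c(0, 0, 0),
                    c(10, 11, 12))
  expect_equal(path_length_km(trk)$total_km,
               2 * great_circle_km(0, 10, 0, 11), tolerance = 1e-9)

  # reversing the track leaves the length unchanged
  rev_trk <- trk |> dplyr::mutate(lat = rev(lat), lon = rev(lon))
  expect_equal(path_length_km(rev_trk)$total_km, path_length_km(trk)$total_km)

  one_fix <- trk[1, ]
  expect_equal(path_length_km(one_fix)$total_km, 0)
  same <- make_fixes("b1", kst("2017-01-01") + (0:1) * 3600, c(40, 40),
                     c(130, 130))
  expect_equal(path_length_km(same)$total_km, 0)
})

test_that("regularization interpolates on the polyline without extrapolating", {
  # two fixes 48 h apart, daily interval: three positions, middle at the
  # great-circle midpoint
  trk <- make_fixes("b1", kst("2017-05-01 00:00") + c(0, 48) * 3600,
                    c(40, 44), c(130, 134))
  reg <- regularize_track(trk, interval_h = 24)
  expect_equal(nrow(reg), 3)
  # oracle: normalized chord midpoint of the two position unit vectors
  to_xyz <- function(lat, lon) {
    p <- lat * pi / 180; l <- lon * pi / 180
    c(cos(p) * cos(l), cos(p) * sin(l), sin(p))
  }
  vm <- to_xyz(40, 130) + to_xyz(44, 134)
  vm <- vm / sqrt(sum(vm^2))
  mid <- c(atan2(vm[2], vm[1]), asin(vm[3])) * 180 / pi  # lon, lat
  expect_lt(great_circle_km(reg$lat[2], reg$lon[2], mid[2], mid[1]), 0.001)
  expect_equal(reg$lat[c(1, 3)], c(40, 44), tolerance = 1e-9)

  # an already-daily track is returned unchanged
  daily <- straight_track(n = 5, step_h = 24)
  reg2 <- regularize_track(daily, interval_h = 24)
  expect_equal(reg2$lat, daily$lat, tolerance = 1e-9)
  expect_equal(reg2$lon, daily$lon, tolerance = 1e-9)

  # random 2 h track: every output point lies on the source polyline (< 1 m)
  # and within the observed time range
  set.seed(21)
  n <- 40
  trk3 <- make_fixes("b1", kst("2017-05-01 00:00") + (0:(n - 1)) * 7200,
                     40 + cumsum(runif(n, 0, 0.3)),
                     130 + cumsum(runif(n, -0.2, 0.4)))
  reg3 <- regularize_track(trk3, interval_h = 24)
  expect_true(all(reg3$timestamp >= min(trk3$timestamp) &
                    reg3$timestamp <= max(trk3$timestamp)))
  for (i in seq_len(nrow(reg3))) {
    expect_lt(point_to_polyline_km(reg3$lat[i], reg3$lon[i],
                                   trk3$lat, trk3$lon), 0.001)
  }
  # resampled points on the polyline can only shorten the path
  expect_lte(path_length_km(reg3)$total_km,
             path_length_km(trk3)$total_km + 1e-9)
})

test_that("LAEA projection is azimuthal, equal-area and invertible", {
  ctr <- list(lat = 55, lon = 145)
  at_ctr <- laea_project(55, 145, ctr)
  expect_equal(c(at_ctr$x_km, at_ctr$y_km), c(0, 0), tolerance = 1e-9)

  # a point due north of the center projects onto the +y axis at its
  # great-circle distance
  north <- laea_inverse(0, 100, ctr)
  expect_equal(north$lon, 145, tolerance = 1e-6)
  # the projection is equal-area, not equidistant: planar radius 100 km is
  # a true distance of 2R asin(50/R) ~ 100.001 km
  expect_equal(great_circle_km(north$lat, north$lon, 55, 145), 100,
               tolerance = 1e-4)

  # round-trip < 1 m within 6000 km of the center
  set.seed(31)
  lat <- runif(200, 10, 85); lon <- runif(200, 100, 190)
  keep <- great_circle_km(lat, wrap_lon(lon), 55, 145) < 6000
  p <- laea_project(lat[keep], wrap_lon(lon[keep]), ctr)
  back <- laea_inverse(p$x_km, p$y_km, ctr)
  expect_lt(max(great_circle_km(back$lat, back$lon, lat[keep],
                                wrap_lon(lon[keep]))), 0.001)

  expect_error(laea_project(-55, -35, ctr), "antipodal")

  # area of a projected 1x1 degree cell at 60N matches the spherical cell
  # area (R^2 * dlon * (sin lat2 - sin lat1)) within 0.1%
  cell_lat <- c(seq(60, 61, length.out = 50), rep(61, 50),
                seq(61, 60, length.out = 50), rep(60, 50))
  cell_lon <- c(rep(150, 50), seq(150, 151, length.out = 50),
                rep(151, 50), seq(151, 150, length.out = 50))
  pc <- laea_project(cell_lat, cell_lon, ctr)
  shoelace <- function(x, y) {
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  }
  proj_area <- shoelace(pc$x_km, pc$y_km)
  sph_area <- 6371.0088^2 * (pi / 180) * (sin(61 * pi / 180) - sin(60 * pi / 180))
  expect_lt(abs(proj_area - sph_area) / sph_area, 0.001)

  # local planar distances approximate great-circle distances within 1%
  set.seed(41)
  la <- runif(50, 53, 57); lo <- runif(50, 141, 149)
  pr <- laea_project(la, lo, ctr)
  for (k in 1:20) {
    i <- sample(50, 2)
    gc <- great_circle_km(la[i[1]], lo[i[1]], la[i[2]], lo[i[2]])
    pl <- sqrt(diff(pr$x_km[i])^2 + diff(pr$y_km[i])^2)
    if (gc > 1 && gc <= 500) expect_lt(abs(pl - gc) / gc, 0.01)
  }
})
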
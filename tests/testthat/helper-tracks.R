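# Shared fixture builders and independent oracles for the test suite.

kst <- function(x) as.POSIXct(x, tz = "Etc/GMT-9")

make_fixes <- function(bird_id, timestamp, lat, lon,
                       altitude_m = NA_real_, voltage_v = NA_real_) {
  tibble::tibble(
    bird_id = bird_id,
    timestamp = lubridate::with_tz(timestamp, "UTC"),
    lat = lat, lon = lon,
    altitude_m = rep_len(altitude_m, length(lat)),
    voltage_v = rep_len(voltage_v, length(lat))
  )
}

# a straight-line track of n fixes every step_h hours, moving north
straight_track <- function(bird = "b1", n = 10, step_h = 2,
                           lat0 = 40, lon0 = 130, dlat = 0.5,
                           start = kst("2017-05-01 00:00")) {
  make_fixes(bird, start + (seq_len(n) - 1) * step_h * 3600,
             lat0 + (seq_len(n) - 1) * dlat, rep(lon0, n))
}

# Hand-written haversine, independent of the implementation route
# (which delegates to geosphere).
haversine_oracle <- function(lat1, lon1, lat2, lon2, r = 6371.0088) {
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dp <- (lat2 - lat1) * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  a <- sin(dp / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# Brute-force DTW by recursive enumeration of all monotone alignment paths.
dtw_brute <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  rec <- function(i, j) {
    if (i == 1 && j == 1) return(cost[1, 1])
    best <- Inf
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    cost[i, j] + best
  }
  rec(n, m)
}

euclid_cost <- function(a, b) {
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  sqrt(dx^2 + dy^2)
}

# Minimum distance (km) from a point to the polyline through the rows of
# (poly_lat, poly_lon): cross-track distance to each segment's great circle
# when the foot point lies within the segment, endpoint distance otherwise.
point_to_polyline_km <- function(plat, plon, poly_lat, poly_lon) {
  r <- 6371.0088
  p <- cbind(plon, plat)
  best <- Inf
  for (k in seq_len(length(poly_lat) - 1)) {
    a <- c(poly_lon[k], poly_lat[k])
    b <- c(poly_lon[k + 1], poly_lat[k + 1])
    seg_len <- geosphere::distHaversine(a, b, r = r)
    along <- geosphere::alongTrackDistance(a, b, p, r = r)
    d <- if (is.finite(along) && along >= 0 && along <= seg_len) {
      abs(geosphere::dist2gc(a, b, p, r = r))
    } else {
      min(geosphere::distHaversine(a, p, r = r),
          geosphere::distHaversine(b, p, r = r))
    }
    best <- min(best, d)
  }
  best
}
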
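#' Great-circle distance between points on the sphere
#'
#' Haversine distance on a sphere of radius 6371.0088 km (IUGG mean Earth
#' radius). Vectorized over all four arguments.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance(s) in kilometers.
#' @examples
#' great_circle_km(68.833, 170.500, 37.390, 129.240)
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  if (n == 0) return(numeric(0))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_KM)
}

#' Normalize longitudes to [-180, 180)
#'
#' @param lon Longitudes in decimal degrees.
#' @return Longitudes wrapped into `[-180, 180)`.
#' @export
wrap_lon <- function(lon) {
  ((lon + 180) %% 360) - 180
}

# lat/lon (degrees) -> unit vectors, one row per point
latlon_to_xyz <- function(lat, lon) {
  phi <- lat * pi / 180
  lam <- lon * pi / 180
  cbind(cos(phi) * cos(lam), cos(phi) * sin(lam), sin(phi))
}

xyz_to_latlon <- function(v) {
  v <- v / sqrt(rowSums(v^2))
  tibble::tibble(
    lat = asin(pmin(1, pmax(-1, v[, 3]))) * 180 / pi,
    lon = wrap_lon(atan2(v[, 2], v[, 1]) * 180 / pi)
  )
}

#' Spherical mean position
#'
#' Mean of geographic positions computed as the normalized 3-D unit-vector
#' mean, so that clusters spanning the antimeridian average correctly
#' (important for Chukotka tracks approaching 180°E).
#'
#' @param lat,lon Coordinates in decimal degrees.
#' @return A one-row tibble with columns `lat` and `lon`.
#' @export
spherical_mean <- function(lat, lon) {
  stopifnot(length(lat) == length(lon))
  keep <- is.finite(lat) & is.finite(lon)
  lat <- lat[keep]; lon <- lon[keep]
  if (length(lat) == 0) stop("spherical_mean(): no finite positions")
  v <- colMeans(latlon_to_xyz(lat, lon))
  r <- sqrt(sum(v^2))
  if (r < 1e-12) stop("spherical_mean(): zero resultant vector, mean undefined")
  xyz_to_latlon(matrix(v, nrow = 1))
}

#' Cumulative track length
#'
#' Sum of consecutive-fix great-circle distances, per bird.
#'
#' @param fixes A fix table with columns `bird_id`, `timestamp`, `lat`, `lon`.
#' @return A tibble with `bird_id` and `total_km` (0 for birds with < 2 fixes).
#' @export
path_length_km <- function(fixes) {
  fixes |>
    dplyr::arrange(.data$bird_id, .data$timestamp) |>
    dplyr::group_by(.data$bird_id) |>
    dplyr::summarise(
      total_km = sum(great_circle_km(
        .data$lat[-dplyr::n()], .data$lon[-dplyr::n()],
        .data$lat[-1], .data$lon[-1]
      )),
      .groups = "drop"
    ) |>
    dplyr::mutate(total_km = ifelse(is.na(.data$total_km), 0, .data$total_km))
}

# Per-step table: one row per consecutive fix pair within a bird.
# Columns: bird_id, t1, t2, lat1/lon1/alt1, lat2/lon2/alt2, dt_h, dist_km.
step_table <- function(fixes) {
  has_alt <- "altitude_m" %in% names(fixes)
  fixes |>
    dplyr::arrange(.data$bird_id, .data$timestamp) |>
    dplyr::group_by(.data$bird_id) |>
    dplyr::mutate(
      t2 = dplyr::lead(.data$timestamp),
      lat2 = dplyr::lead(.data$lat),
      lon2 = dplyr::lead(.data$lon),
      alt2 = if (has_alt) dplyr::lead(.data$altitude_m) else NA_real_
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$t2)) |>
    dplyr::transmute(
      bird_id = .data$bird_id,
      t1 = .data$timestamp, t2 = .data$t2,
      lat1 = .data$lat, lon1 = .data$lon,
      alt1 = if (has_alt) .data$altitude_m else NA_real_,
      lat2 = .data$lat2, lon2 = .data$lon2, alt2 = .data$alt2,
      dt_h = as.numeric(difftime(.data$t2, .data$t1, units = "hours")),
      dist_km = great_circle_km(.data$lat1, .data$lon1, .data$lat2, .data$lon2)
    )
}

# Spherical linear interpolation between unit vectors a and b at fractions f.
# a, b: single unit vectors; f: vector of fractions in [0, 1].
slerp <- function(a, b, f) {
  dotab <- sum(a * b)
  omega <- acos(pmin(1, pmax(-1, dotab)))
  if (omega < 1e-12) {
    return(matrix(rep(a, each = length(f)), ncol = 3))
  }
  so <- sin(omega)
  wa <- sin((1 - f) * omega) / so
  wb <- sin(f * omega) / so
  cbind(wa * a[1] + wb * b[1], wa * a[2] + wb * b[2], wa * a[3] + wb * b[3])
}

#' Regularize tracks to a fixed time interval
#'
#' Resamples each bird's track to positions at exact multiples of `interval_h`
#' hours from its first fix, by linear interpolation in time along the
#' great-circle segment between the bracketing fixes. Output never
#' extrapolates beyond the observed time range. Positions interpolated across
#' a data gap longer than `gap_flag_days` are kept but flagged.
#'
#' @param fixes A fix table (`bird_id`, `timestamp`, `lat`, `lon`).
#' @param interval_h Resampling interval in hours (default 24: daily track).
#' @param gap_flag_days Gaps longer than this many days are flagged in the
#'   `gap` column (default 7).
#' @return A tibble with `bird_id`, `timestamp`, `lat`, `lon`, `gap`.
#' @export
regularize_track <- function(fixes, interval_h = 24, gap_flag_days = 7) {
  stopifnot(interval_h > 0)
  fixes |>
    dplyr::arrange(.data$bird_id, .data$timestamp) |>
    dplyr::group_by(.data$bird_id) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 2) {
        return(tibble::tibble(timestamp = df$timestamp,
                              lat = df$lat, lon = df$lon, gap = FALSE))
      }
      t <- as.numeric(df$timestamp)
      step <- interval_h * 3600
      targets <- seq(t[1], t[length(t)], by = step)
      idx <- findInterval(targets, t, rightmost.closed = TRUE)
      idx <- pmin(idx, length(t) - 1)
      f <- (targets - t[idx]) / (t[idx + 1] - t[idx])
      v <- latlon_to_xyz(df$lat, df$lon)
      out <- matrix(NA_real_, length(targets), 3)
      for (k in seq_along(targets)) {
        out[k, ] <- slerp(v[idx[k], ], v[idx[k] + 1, ], f[k])
      }
      ll <- xyz_to_latlon(out)
      tibble::tibble(
        timestamp = as.POSIXct(targets, origin = "1970-01-01", tz = "UTC"),
        lat = ll$lat, lon = ll$lon,
        gap = (t[idx + 1] - t[idx]) > gap_flag_days * 86400 & f > 0 & f < 1
      )
    }) |>
    dplyr::ungroup()
}

#' Lambert azimuthal equal-area projection (spherical)
#'
#' Forward projection onto a plane tangent at `center`, in kilometers. The
#' projection is exactly area-preserving on the sphere; round-trip error via
#' [laea_inverse()] is below 1 m within 6000 km of the center.
#'
#' @param lat,lon Coordinates in decimal degrees.
#' @param center A list or one-row data frame with `lat` and `lon` of the
#'   projection origin.
#' @return A tibble with `x_km`, `y_km`.
#' @export
laea_project <- function(lat, lon, center) {
  phi1 <- center$lat * pi / 180
  lam0 <- center$lon * pi / 180
  phi <- lat * pi / 180
  lam <- lon * pi / 180
  cosc <- sin(phi1) * sin(phi) + cos(phi1) * cos(phi) * cos(lam - lam0)
  if (any(cosc <= -1 + 1e-12, na.rm = TRUE)) {
    stop("laea_project(): point antipodal to projection center")
  }
  kp <- sqrt(2 / (1 + cosc))
  tibble::tibble(
    x_km = EARTH_RADIUS_KM * kp * cos(phi) * sin(lam - lam0),
    y_km = EARTH_RADIUS_KM * kp *
      (cos(phi1) * sin(phi) - sin(phi1) * cos(phi) * cos(lam - lam0))
  )
}

#' @rdname laea_project
#' @param x_km,y_km Projected coordinates in kilometers.
#' @export
laea_inverse <- function(x_km, y_km, center) {
  phi1 <- center$lat * pi / 180
  lam0 <- center$lon * pi / 180
  rho <- sqrt(x_km^2 + y_km^2)
  c <- 2 * asin(pmin(1, rho / (2 * EARTH_RADIUS_KM)))
  lat <- ifelse(
    rho < 1e-12, phi1,
    asin(pmin(1, pmax(-1, cos(c) * sin(phi1) +
                        y_km * sin(c) * cos(phi1) / ifelse(rho < 1e-12, 1, rho))))
  )
  lon <- lam0 + atan2(
    x_km * sin(c),
    rho * cos(phi1) * cos(c) - y_km * sin(phi1) * sin(c)
  )
  lon <- ifelse(rho < 1e-12, lam0, lon)
  tibble::tibble(lat = lat * 180 / pi, lon = wrap_lon(lon * 180 / pi))
}
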
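#' Apparent solar elevation
#'
#' Solar elevation angle (degrees above the horizon) at a geographic position
#' and instant, corrected for standard atmospheric refraction. Uses the NOAA
#' solar-calculator formulation (Meeus low-accuracy solar position): accurate
#' to well under 0.1 degrees for years 1900-2100, which is far below the
#' precision needed to classify civil twilight.
#'
#' @param lat,lon Position in decimal degrees. Vectorized.
#' @param time A POSIXct instant (any time zone; converted internally to UTC).
#' @return Apparent solar elevation in degrees, in `[-90, 90]`.
#' @examples
#' solar_elevation(37.390, 129.240, as.POSIXct("2017-03-20 03:00", tz = "UTC"))
#' @export
solar_elevation <- function(lat, lon, time) {
  stopifnot(inherits(time, "POSIXct"))
  n <- max(length(lat), length(lon), length(time))
  lat <- rep_len(lat, n); lon <- rep_len(lon, n)
  time <- rep_len(time, n)

  d2r <- pi / 180
  jd <- as.numeric(time) / 86400 + 2440587.5
  tc <- (jd - 2451545) / 36525  # Julian centuries from J2000

  # Geometric mean longitude / anomaly of the sun, eccentricity
  l0 <- (280.46646 + tc * (36000.76983 + tc * 0.0003032)) %% 360
  m <- 357.52911 + tc * (35999.05029 - 0.0001537 * tc)
  ecc <- 0.016708634 - tc * (0.000042037 + 0.0000001267 * tc)

  # Equation of center, true and apparent longitude
  ctr <- sin(m * d2r) * (1.914602 - tc * (0.004817 + 0.000014 * tc)) +
    sin(2 * m * d2r) * (0.019993 - 0.000101 * tc) +
    sin(3 * m * d2r) * 0.000289
  true_long <- l0 + ctr
  omega <- 125.04 - 1934.136 * tc
  app_long <- true_long - 0.00569 - 0.00478 * sin(omega * d2r)

  # Obliquity (corrected) and solar declination
  e0 <- 23 + (26 + (21.448 - tc * (46.815 + tc * (0.00059 - tc * 0.001813))) / 60) / 60
  obliq <- e0 + 0.00256 * cos(omega * d2r)
  decl <- asin(sin(obliq * d2r) * sin(app_long * d2r)) / d2r

  # Equation of time, minutes
  y <- tan(obliq / 2 * d2r)^2
  eqtime <- 4 / d2r * (
    y * sin(2 * l0 * d2r) - 2 * ecc * sin(m * d2r) +
      4 * ecc * y * sin(m * d2r) * cos(2 * l0 * d2r) -
      0.5 * y^2 * sin(4 * l0 * d2r) - 1.25 * ecc^2 * sin(2 * m * d2r)
  )

  # True solar time -> hour angle
  utc_min <- (jd + 0.5 - floor(jd + 0.5)) * 1440
  tst <- (utc_min + eqtime + 4 * lon) %% 1440
  ha <- tst / 4 - 180

  cos_zen <- sin(lat * d2r) * sin(decl * d2r) +
    cos(lat * d2r) * cos(decl * d2r) * cos(ha * d2r)
  elev <- 90 - acos(pmin(1, pmax(-1, cos_zen))) / d2r

  elev + refraction_correction(elev)
}

# NOAA standard atmospheric refraction correction, degrees, as a function of
# geometric elevation (degrees).
refraction_correction <- function(elev) {
  te <- tan(elev * pi / 180)
  corr <- numeric(length(elev))
  hi <- elev > 5 & elev <= 85
  corr[hi] <- (58.1 / te[hi] - 0.07 / te[hi]^3 + 0.000086 / te[hi]^5) / 3600
  mid <- elev > -0.575 & elev <= 5
  e <- elev[mid]
  corr[mid] <- (1735 + e * (-518.2 + e * (103.4 + e * (-12.79 + e * 0.711)))) / 3600
  lo <- elev <= -0.575
  corr[lo] <- (-20.774 / te[lo]) / 3600
  corr
}

#' Diel class of a bout
#'
#' Classifies a bout (a leg between two consecutive fixes) as day, twilight or
#' night from the apparent solar elevation at each endpoint's own position and
#' instant: night when both endpoints are below the threshold, day when both
#' are at or above it, twilight when the bout starts in one regime and ends in
#' the other. The default threshold of -6 degrees is the civil-twilight limit
#' (sun 0 to 6 degrees below the horizon is twilight, hence "night" below
#' -6).
#'
#' @param elev_start,elev_end Apparent solar elevations (degrees) at the bout
#'   endpoints. Vectorized.
#' @param threshold_deg Signed elevation threshold in degrees (default -6).
#' @return A character vector with values `"day"`, `"twilight"`, `"night"`.
#' @export
classify_diel <- function(elev_start, elev_end, threshold_deg = -6) {
  s <- elev_start < threshold_deg
  e <- elev_end < threshold_deg
  dplyr::case_when(
    s & e ~ "night",
    !s & !e ~ "day",
    TRUE ~ "twilight"
  )
}
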
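# Frozen oracle elevations computed with an independently coded
# implementation of the published NOAA solar-calculator algorithm
# (refraction-corrected apparent elevation, degrees).
solar_fixture <- list(
  list(lat = 37.39, lon = 129.24, time = "2017-03-20 03:00", elev = 51.8435),
  list(lat = 37.39, lon = 129.24, time = "2017-06-21 09:30", elev = 13.0801),
  list(lat = 37.39, lon = 129.24, time = "2017-12-21 21:00", elev = -18.0124),
  list(lat = 68.833, lon = 170.5, time = "2018-06-21 01:00", elev = 44.5137),
  list(lat = 68.833, lon = 170.5, time = "2018-12-21 13:00", elev = -44.4513),
  list(lat = 45.0, lon = 140.0, time = "2016-09-22 20:30", elev = 0.0555)
)
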
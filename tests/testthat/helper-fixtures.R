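# Fixtures built in code; no files on disk.

utc <- function(x) as.POSIXct(x, tz = "UTC")

# A straight south-to-north track over the reference meridian of a coastline.
meridian_track <- function(lat_from, lat_to, t_from, t_to, lon = 16) {
  data.frame(t = c(utc(t_from), utc(t_to)), lon = lon, lat = c(lat_from, lat_to))
}

strait_coast <- function(width_km = 200) generate_coastline("strait", width_km)

# Frozen outputs of an independent Python transcription of the NOAA
# solar-calculator spreadsheet algorithm (minutes UTC after midnight).
noaa_oracle <- data.frame(
  lat = c(0, 57.34, 36, 56.2, 0),
  lon = c(0, 16.21, 5, 16.4, 0),
  date = as.Date(c("2020-03-20", "2020-09-05", "2021-04-20",
                   "2020-12-21", "2020-06-21")),
  rise_min = c(364.044, 245.541, 300.383, 445.617, 358.223),
  set_min = c(1090.558, 1060.556, 1097.929, 859.769, 1085.595))
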
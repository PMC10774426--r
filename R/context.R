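#' Solar elevation angle
#'
#' Low-accuracy (about 0.01 degree) solar position from the standard
#' NOAA/Meeus series: apparent solar longitude and obliquity give the
#' declination, the equation of time gives true solar time, and elevation
#' follows from the hour angle. Sufficient by a wide margin for day/night
#' classification.
#'
#' @param time POSIXct (UTC).
#' @param lat,lon decimal degrees (north/east positive).
#' @return Solar elevation above the horizon, degrees (no refraction).
#' @export
solar_elevation <- function(time, lat, lon) {
  if (any(abs(lat) > 90)) stopf("latitude out of range: %g", lat[abs(lat) > 90][1])
  if (any(abs(lon) > 360)) stopf("longitude out of range: %g", lon[abs(lon) > 360][1])
  d2r <- pi / 180
  jd <- as.numeric(as_utc(time)) / 86400 + 2440587.5
  T <- (jd - 2451545) / 36525
  L0 <- (280.46646 + 36000.76983 * T + 0.0003032 * T^2) %% 360
  M <- (357.52911 + 35999.05029 * T - 0.0001537 * T^2) %% 360
  e <- 0.016708634 - 0.000042037 * T
  C <- (1.914602 - 0.004817 * T - 0.000014 * T^2) * sin(M * d2r) +
    (0.019993 - 0.000101 * T) * sin(2 * M * d2r) + 0.000289 * sin(3 * M * d2r)
  Omega <- 125.04 - 1934.136 * T
  lambda <- L0 + C - 0.00569 - 0.00478 * sin(Omega * d2r)
  eps0 <- 23 + 26 / 60 + 21.448 / 3600 -
    (46.815 * T + 0.00059 * T^2 - 0.001813 * T^3) / 3600
  eps <- eps0 + 0.00256 * cos(Omega * d2r)
  decl <- asin(sin(eps * d2r) * sin(lambda * d2r)) / d2r
  y <- tan(eps / 2 * d2r)^2
  eot <- 4 / d2r * (y * sin(2 * L0 * d2r) - 2 * e * sin(M * d2r) +
                      4 * e * y * sin(M * d2r) * cos(2 * L0 * d2r) -
                      0.5 * y^2 * sin(4 * L0 * d2r) -
                      1.25 * e^2 * sin(2 * M * d2r))     # minutes
  mins <- (jd + 0.5) %% 1 * 1440                          # UTC minutes of day
  tst <- (mins + eot + 4 * lon) %% 1440
  ha <- tst / 4 - 180
  asin(sin(lat * d2r) * sin(decl * d2r) +
         cos(lat * d2r) * cos(decl * d2r) * cos(ha * d2r)) / d2r
}

#' Day or night at a timestamp and location
#'
#' Day is defined by the sun being above the geometric horizon (solar
#' elevation > 0), not civil twilight.
#'
#' @inheritParams solar_elevation
#' @return character vector, `"day"` or `"night"`.
#' @examples
#' day_night(as.POSIXct("2022-01-15 09:00:00", tz = "UTC"), -49.35, 70.22)
#' @export
day_night <- function(time, lat, lon) {
  ifelse(solar_elevation(time, lat, lon) > 0, "day", "night")
}

#' Assign a behavioral context to each ingestion event
#'
#' The context is decided at the thermal minimum T2, the instant closest
#' to the ingestion itself: inside a detected dive it is `diving`, inside
#' a surface swim `surface_swimming`, inside a wallow or while dry
#' `on_land`, and `unknown` when the wet sensor indicates water contact
#' without a detected submersion event. A `day` column is added when the
#' series carries colony coordinates.
#'
#' @param ingestions an `ingestion_events` data.frame.
#' @param events the individual's `atsea_events`.
#' @param series the [sensor_series] both were detected in.
#' @param at anchor instant, `"t_T2"` (default) or `"t_T1"`.
#' @return `ingestions` with added `context` and `day` columns.
#' @export
assign_context <- function(ingestions, events, series, at = c("t_T2", "t_T1")) {
  at <- match.arg(at)
  if (!nrow(ingestions)) {
    ingestions$context <- character(0)
    ingestions$day <- logical(0)
    return(ingestions)
  }
  anchor <- ingestions[[at]]
  span <- range(series$timestamp)
  if (any(anchor < span[1] | anchor > span[2]))
    stopf("ingestion events fall outside the sensor record: clock mismatch?")
  idx <- findInterval(as.numeric(anchor), as.numeric(series$timestamp))
  ctx <- character(nrow(ingestions))
  for (r in seq_len(nrow(ingestions))) {
    hit <- which(events$start <= anchor[r] & anchor[r] < events$end)
    if (length(hit)) {
      ctx[r] <- switch(events$kind[hit[1L]],
                       dive = "diving",
                       surface_swim = "surface_swimming",
                       wallow = "on_land")
    } else if (isTRUE(series$wet[idx[r]])) {
      ctx[r] <- "unknown"
    } else {
      ctx[r] <- "on_land"
    }
  }
  ingestions$context <- ctx
  lat <- attr(series, "lat"); lon <- attr(series, "lon")
  ingestions$day <- if (!is.na(lat) && !is.na(lon)) {
    day_night(anchor, lat, lon) == "day"
  } else NA
  ingestions
}

#' Latency from hyperthermia events to the next at-sea event
#'
#' For each hyperthermia event, the time from its end to the start of the
#' next at-sea event (dive or surface swim); `NA` when no later event
#' exists. Two hyperthermia events may share the same subsequent at-sea
#' event.
#'
#' @param hyper a `hyperthermia_events` data.frame.
#' @param events the individual's `atsea_events`.
#' @return `hyper` with an added `latency_to_sea_h` column (hours).
#' @export
hyperthermia_latency <- function(hyper, events) {
  atsea <- events[events$kind %in% c("dive", "surface_swim"), , drop = FALSE]
  hyper$latency_to_sea_h <- vapply(seq_len(nrow(hyper)), function(i) {
    nxt <- atsea$start[atsea$start >= hyper$end[i]]
    if (!length(nxt)) return(NA_real_)
    secs(hyper$end[i], min(nxt)) / 3600
  }, numeric(1))
  hyper
}
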
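#' Construct a multi-sensor biologging series
#'
#' A `sensor_series` is a data frame with one row per 10-s sample and
#' columns `timestamp` (POSIXct, UTC), `depth_m` (positive downward),
#' `light` (instrument units in \[0, 255\]), `wet` (logical) and
#' `stomach_temp_c` (degC, `NA` allowed: pill not yet swallowed, ejected,
#' or removed by QC). Individual metadata (id, capture/recapture times,
#' colony coordinates) travel as attributes.
#'
#' @param timestamp POSIXct (or parseable) sample instants, strictly
#'   increasing, UTC.
#' @param depth_m numeric depth in meters, positive downward.
#' @param light numeric light level, instrument units in \[0, 255\].
#' @param wet logical (or 0/1) wet/dry sensor state.
#' @param stomach_temp_c numeric stomach temperature in degC, or `NULL` for
#'   TDR-only individuals.
#' @param individual_id character id.
#' @param capture_time,recapture_time POSIXct or `NULL`.
#' @param lat,lon colony coordinates in decimal degrees.
#' @param validate run structural validation (default `TRUE`).
#' @return A data frame of class `sensor_series`.
#' @export
sensor_series <- function(timestamp, depth_m, light, wet,
                          stomach_temp_c = NULL,
                          individual_id = "unknown",
                          capture_time = NULL, recapture_time = NULL,
                          lat = NA_real_, lon = NA_real_,
                          validate = TRUE) {
  timestamp <- as_utc(timestamp)
  n <- length(timestamp)
  if (is.null(stomach_temp_c)) stomach_temp_c <- rep(NA_real_, n)
  x <- data.frame(timestamp = timestamp,
                  depth_m = as.numeric(depth_m),
                  light = as.numeric(light),
                  wet = as.logical(wet),
                  stomach_temp_c = as.numeric(stomach_temp_c))
  attr(x, "individual_id") <- individual_id
  attr(x, "capture_time") <- if (!is.null(capture_time)) as_utc(capture_time)
  attr(x, "recapture_time") <- if (!is.null(recapture_time)) as_utc(recapture_time)
  attr(x, "lat") <- lat
  attr(x, "lon") <- lon
  class(x) <- c("sensor_series", "data.frame")
  if (validate) validate_sensor_series(x)
  x
}

#' @rdname sensor_series
#' @param x a `sensor_series`.
#' @export
validate_sensor_series <- function(x) {
  n <- nrow(x)
  if (n == 0L) stopf("sensor series is empty")
  ts <- as.numeric(x$timestamp)
  if (anyNA(ts)) stopf("unparseable timestamp at row %d", which(is.na(ts))[1L])
  d <- diff(ts)
  bad <- which(d <= 0)
  if (length(bad)) {
    stopf("timestamps not strictly increasing: row %d (%s) does not follow row %d",
          bad[1L] + 1L, format(x$timestamp[bad[1L] + 1L], "%Y-%m-%dT%H:%M:%SZ"),
          bad[1L])
  }
  lt <- x$light
  out <- which(!is.na(lt) & (lt < 0 | lt > 255))
  if (length(out)) {
    stopf("light level out of [0, 255] at row %d (value %g)", out[1L], lt[out[1L]])
  }
  invisible(x)
}

#' Nominal sampling cadence of a series, in seconds
#'
#' The most common timestamp spacing (nominally 10 s).
#' @param x a `sensor_series`.
#' @return seconds between samples.
#' @export
series_cadence <- function(x) {
  d <- diff(as.numeric(x$timestamp))
  if (!length(d)) return(10)
  tab <- table(d)
  as.numeric(names(tab)[which.max(tab)])
}

#' Read a multi-sensor CSV record
#'
#' Expects columns `timestamp` (ISO-8601, UTC), `depth_m`, `light`, `wet`
#' (0/1) and optionally `stomach_temp_c` (empty cells allowed). Timestamps
#' must be strictly increasing; violations are reported with the first
#' offending row.
#'
#' @param path path to the CSV file.
#' @param individual_id id recorded in the result; defaults to the file
#'   name without extension.
#' @param capture_time,recapture_time optional POSIXct metadata.
#' @param lat,lon colony coordinates in decimal degrees.
#' @return A [sensor_series].
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' t0 <- as.POSIXct("2022-01-10 00:00:00", tz = "UTC")
#' write_sensor_series(sensor_series(t0 + seq(0, 90, 10), depth_m = 0,
#'                                   light = 100, wet = FALSE), tf)
#' s <- read_sensor_series(tf, individual_id = "demo")
#' nrow(s)
#' @export
read_sensor_series <- function(path, individual_id = NULL,
                               capture_time = NULL, recapture_time = NULL,
                               lat = NA_real_, lon = NA_real_) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) stopf("cannot parse %s: %s", path,
                                            conditionMessage(e)))
  if (nrow(raw) == 0L) stopf("empty sensor file: %s", path)
  need <- c("timestamp", "depth_m", "light", "wet")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stopf("missing column(s): %s", paste(miss, collapse = ", "))
  ts <- as_utc(raw$timestamp)
  if (anyNA(ts)) stopf("unparseable timestamp at row %d", which(is.na(ts))[1L])
  stp <- if ("stomach_temp_c" %in% names(raw)) raw$stomach_temp_c else NULL
  sensor_series(ts, raw$depth_m, raw$light, raw$wet, stp,
                individual_id = individual_id %||%
                  sub("\\.[^.]*$", "", basename(path)),
                capture_time = capture_time, recapture_time = recapture_time,
                lat = lat, lon = lon)
}

#' Write a series back to CSV
#'
#' Inverse of [read_sensor_series()]; timestamps are written as ISO-8601
#' UTC and `wet` as 0/1.
#'
#' @param x a `sensor_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sensor_series <- function(x, path) {
  out <- data.frame(timestamp = format(x$timestamp, "%Y-%m-%dT%H:%M:%SZ"),
                    depth_m = x$depth_m, light = x$light,
                    wet = as.integer(x$wet),
                    stomach_temp_c = x$stomach_temp_c)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.sensor_series <- function(x, ...) {
  span <- range(x$timestamp)
  cat(sprintf("<sensor_series> individual %s: %d samples at %gs cadence\n",
              attr(x, "individual_id") %||% "?", nrow(x), series_cadence(x)))
  cat(sprintf("  %s .. %s (%.2f days)\n",
              format(span[1], "%Y-%m-%d %H:%M:%S"),
              format(span[2], "%Y-%m-%d %H:%M:%S"),
              secs(span[1], span[2]) / 86400))
  cat(sprintf("  depth %.1f..%.1f m | light %.0f..%.0f | wet %.1f%% | stomach temp %s\n",
              min(x$depth_m, na.rm = TRUE), max(x$depth_m, na.rm = TRUE),
              min(x$light, na.rm = TRUE), max(x$light, na.rm = TRUE),
              100 * mean(x$wet, na.rm = TRUE),
              if (all(is.na(x$stomach_temp_c))) "absent" else
                sprintf("%.1f..%.1f degC", min(x$stomach_temp_c, na.rm = TRUE),
                        max(x$stomach_temp_c, na.rm = TRUE))))
  invisible(x)
}

#' Subset a series to a half-open time window \[from, to)
#' @param x a `sensor_series`.
#' @param from,to POSIXct bounds; `NULL` leaves that side open.
#' @return the windowed `sensor_series`.
#' @export
series_window <- function(x, from = NULL, to = NULL) {
  keep <- rep(TRUE, nrow(x))
  if (!is.null(from)) keep <- keep & x$timestamp >= as_utc(from)
  if (!is.null(to)) keep <- keep & x$timestamp < as_utc(to)
  out <- x[keep, , drop = FALSE]
  attributes(out)[c("individual_id", "capture_time", "recapture_time",
                    "lat", "lon")] <-
    attributes(x)[c("individual_id", "capture_time", "recapture_time",
                    "lat", "lon")]
  class(out) <- class(x)
  rownames(out) <- NULL
  out
}
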
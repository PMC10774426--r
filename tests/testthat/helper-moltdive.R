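## shared fixture builders (all fixtures are generated in code)

T0 <- as.POSIXct("2022-01-10 00:00:00", tz = "UTC")
KERGUELEN <- c(lat = -49.35, lon = 70.22)

## a sensor series from plain channel vectors on a 10 s grid
make_series <- function(n, depth = 0, light = 100, wet = FALSE,
                        stomach = NA_real_, t0 = T0, cadence = 10,
                        capture_time = t0, lat = NA_real_, lon = NA_real_) {
  ts <- t0 + (seq_len(n) - 1L) * cadence
  sensor_series(ts, rep_len(depth, n), rep_len(light, n), rep_len(wet, n),
                rep_len(stomach, n), individual_id = "fix",
                capture_time = capture_time, lat = lat, lon = lon)
}

## stomach-temperature series holding an instantaneous drop of `delta`
## at sample `i0` with exponential recovery at rate k (degC baseline T1)
exp_drop_channel <- function(n, i0, T1 = 37, delta = 5, k = 1 / 600,
                             cadence = 10, noise_sd = 0) {
  x <- rep(T1, n)
  len <- n - i0 + 1L
  x[i0:n] <- T1 - delta * exp(-k * (seq_len(len) - 1L) * cadence)
  if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
  x
}

## independent solar elevation oracle: Spencer (1971) Fourier series for
## declination and equation of time (a different formulation from the
## package's Meeus-style series)
spencer_elevation <- function(time, lat, lon) {
  time <- as.POSIXct(time, tz = "UTC")
  doy <- as.integer(format(time, "%j"))
  hour <- as.numeric(format(time, "%H")) + as.numeric(format(time, "%M")) / 60 +
    as.numeric(format(time, "%S")) / 3600
  g <- 2 * pi / 365 * (doy - 1 + (hour - 12) / 24)
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  eot <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                     0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  tst <- (hour * 60 + eot + 4 * lon) %% 1440
  ha <- (tst / 4 - 180) * pi / 180
  phi <- lat * pi / 180
  asin(sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(ha)) * 180 / pi
}

## minimal hand-built at-sea event table (columns summarize_behavior and
## group_cycles rely on)
make_events <- function(kind, start_s, duration_s, max_depth,
                        t0 = T0, cadence = 10) {
  if (!length(kind)) {
    ev <- moltdive:::atsea_events_frame("fix")
    return(ev)
  }
  start <- t0 + start_s
  end <- start + duration_s
  n <- length(kind)
  ev <- data.frame(event_id = seq_len(n), kind = kind, start = start,
                   end = end, duration_s = duration_s,
                   max_depth_m = max_depth,
                   time_to_max_s = duration_s / 2,
                   light_range = ifelse(kind == "wallow", 2, 40),
                   n_phases = 1L,
                   surface_after_s = c(as.numeric(start[-1] - end[-n],
                                                  units = "secs"), NA),
                   descent_s = NA_real_, bottom_s = NA_real_,
                   ascent_s = NA_real_,
                   start_idx = as.integer(start_s / cadence) + 1L,
                   end_idx = as.integer((start_s + duration_s) / cadence))
  class(ev) <- c("atsea_events", "data.frame")
  ev
}

## match each truth event to the detected event containing its midpoint
match_events <- function(truth, detected) {
  mid <- truth$start + (truth$end - truth$start) / 2
  vapply(seq_along(mid), function(i) {
    hit <- which(detected$start <= mid[i] & mid[i] < detected$end)
    if (length(hit)) hit[1L] else NA_integer_
  }, integer(1))
}
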
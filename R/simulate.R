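#' Simulation configuration
#'
#' Defaults describe a molting female southern elephant seal monitored for
#' a week at a subantarctic colony: 10-s multi-sensor cadence; shallow
#' dives (lognormal maximum depth targeting a 12.5 m mean within 5-43 m,
#' durations targeting 7.7 min) grouped into cycles of mean size 8.6 with
#' short surface intervals; multi-hour surface swims between 1 and 5 m;
#' optically dark mud wallows; stomach temperature around 36.5 degC on
#' land and 0.6 degC warmer at sea, with sensor noise, slow instrument
#' drift, instantaneous-mixing ingestion drops with exponential recovery,
#' and occasional on-land hyperthermia excursions.
#'
#' @param duration_days monitored span, days.
#' @param cadence sampling interval, seconds.
#' @param start_time first timestamp (UTC), austral summer by default.
#' @param lat,lon colony coordinates (Kerguelen).
#' @param dive_rate,swim_rate,wallow_rate expected events per day.
#' @param cycle_size_mean mean number of dives per dive cycle (geometric).
#' @param dive_depth_meanlog,dive_depth_sdlog,dive_depth_range lognormal
#'   maximum-depth law (m), truncated.
#' @param dive_dur_meanlog,dive_dur_sdlog,dive_dur_range lognormal dive
#'   duration law (minutes), truncated.
#' @param surface_meanlog,surface_sdlog,surface_range lognormal
#'   within-cycle surface interval law (minutes), truncated.
#' @param swim_dur_meanlog,swim_dur_sdlog,swim_dur_range lognormal
#'   surface-swim duration law (hours), truncated.
#' @param swim_depth_range,wallow_depth_range,wallow_dur_range_min uniform
#'   ranges for swim depth (m), wallow depth (m) and wallow duration (min).
#' @param land_temp_mean,land_temp_sd across-individual law of the on-land
#'   stomach baseline, degC.
#' @param sea_offset at-sea elevation of the baseline, degC.
#' @param baseline_tau time constant of baseline transitions, s.
#' @param temp_noise_sd stomach sensor noise, degC.
#' @param drift_per_10_days linear instrument drift, degC per 10 days.
#' @param stomach_mass thermal mass of the stomach contents, kg.
#' @param water_temp ingested water temperature, degC.
#' @param ingestion_rate ingestion events per day.
#' @param prey_prob probability an ingestion is a prey item.
#' @param ingest_mass_range kg of ingested matter (uniform).
#' @param k_water_range,k_prey_range recovery rate ranges, 1/s (prey
#'   recoveries are slower).
#' @param context_probs placement probabilities of ingestions across
#'   diving / surface swimming / on land.
#' @param hyper_rate,hyper_amp,hyper_dur_mean_min,hyper_dur_sd_min on-land
#'   hyperthermia excursions: rate per day, amplitude (degC), truncated
#'   normal duration (min).
#' @param night_light,day_light_amp surface light at night and diel
#'   amplitude, instrument units.
#' @param light_attenuation diffuse attenuation of light with depth, 1/m.
#' @param mud_light_range light range rendered inside a mud wallow.
#' @param depth_noise_sd,dry_depth_noise_sd depth sensor noise, m.
#' @param lead_in_s quiet period after the start (capture handling and
#'   post-capture discard window), s.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(duration_days = 7,
                       cadence = 10,
                       start_time = "2022-01-10 00:00:00",
                       lat = -49.35, lon = 70.22,
                       dive_rate = 6, swim_rate = 1.5, wallow_rate = 1,
                       cycle_size_mean = 8.6,
                       dive_depth_meanlog = 2.379, dive_depth_sdlog = 0.542,
                       dive_depth_range = c(5, 43),
                       dive_dur_meanlog = 1.942, dive_dur_sdlog = 0.445,
                       dive_dur_range = c(0.5, 22.5),
                       surface_meanlog = 0.382, surface_sdlog = 0.9,
                       surface_range = c(0.3, 19),
                       swim_dur_meanlog = 0.023, swim_dur_sdlog = 1.06,
                       swim_dur_range = c(0.25, 8),
                       swim_depth_range = c(1.2, 4.5),
                       wallow_depth_range = c(0.6, 1.5),
                       wallow_dur_range_min = c(20, 60),
                       land_temp_mean = 36.5, land_temp_sd = 0.15,
                       sea_offset = 0.6,
                       baseline_tau = 300,
                       temp_noise_sd = 0.05,
                       drift_per_10_days = 0.05,
                       stomach_mass = 5, water_temp = 8,
                       ingestion_rate = 0.4,
                       prey_prob = 0.4,
                       ingest_mass_range = c(0.3, 1.2),
                       k_water_range = c(1 / 450, 1 / 250),
                       k_prey_range = c(1 / 2000, 1 / 900),
                       context_probs = c(diving = 0.15,
                                         surface_swimming = 0.5,
                                         on_land = 0.35),
                       hyper_rate = 0.1, hyper_amp = 1.5,
                       hyper_dur_mean_min = 110, hyper_dur_sd_min = 39,
                       night_light = 40, day_light_amp = 180,
                       light_attenuation = 0.3,
                       mud_light_range = c(2.5, 4.5),
                       depth_noise_sd = 0.03, dry_depth_noise_sd = 0.02,
                       lead_in_s = 6.5 * 3600) {
  stopifnot(duration_days > 0, cadence > 0, dive_rate >= 0, swim_rate >= 0,
            wallow_rate >= 0, ingestion_rate >= 0, hyper_rate >= 0,
            stomach_mass > 0, all(k_water_range > 0), all(k_prey_range > 0))
  cfg <- as.list(environment())
  cfg$context_probs <- context_probs / sum(context_probs)
  structure(cfg, class = "sim_config")
}

rtrunc <- function(n, rfun, lo, hi, ...) {
  out <- rfun(n, ...)
  bad <- which(out < lo | out > hi)
  guard <- 0L
  while (length(bad) && guard < 1000L) {
    out[bad] <- rfun(length(bad), ...)
    bad <- which(out < lo | out > hi)
    guard <- guard + 1L
  }
  pmin(pmax(out, lo), hi)
}

#' Simulate a single ingestion temperature curve
#'
#' Instantaneous-mixing model: ingesting mass `m` at temperature `Tw` into
#' a stomach of thermal mass `M` at `T1` drops the temperature to the
#' mixed minimum `T2 = (M T1 + m Tw) / (M + m)`, after which it recovers
#' exponentially, `T(t) = T1 - (T1 - T2) exp(-k t)`. All event features
#' then have closed forms: half-recovery time `ln 2 / k`, recovery-rate
#' index `(ln 2 / k) / (T1 - T2)`, area above the curve `(T1 - T2) / k`.
#'
#' @param T1 pre-ingestion stomach temperature, degC.
#' @param Tw temperature of the ingested matter, degC.
#' @param m ingested mass, kg (0 gives a flat segment and no event).
#' @param M stomach thermal mass, kg.
#' @param k recovery rate, 1/s.
#' @param cadence sampling interval, s.
#' @param tol deficit (degC) at which the rendered segment ends.
#' @return A list with `temp` (the sampled segment, first sample at the
#'   minimum) and `truth` (`T2`, `delta_T`, `t_half`, `integral`, `k`), or
#'   `truth = NULL` when `m = 0`.
#' @examples
#' simulate_ingestion_curve(37, 8, m = 0.5, M = 2, k = 1/600)$truth$T2
#' @export
simulate_ingestion_curve <- function(T1, Tw, m, M, k, cadence = 10,
                                     tol = 0.01) {
  stopifnot(m >= 0, M > 0, k > 0)
  if (m == 0) {
    return(list(temp = rep(T1, as.integer(600 / cadence)), truth = NULL))
  }
  T2 <- (M * T1 + m * Tw) / (M + m)
  delta <- T1 - T2
  len <- as.integer(ceiling(log(delta / tol) / k / cadence)) + 1L
  t <- (seq_len(len) - 1L) * cadence
  list(temp = T1 - delta * exp(-k * t),
       truth = list(T2 = T2, delta_T = delta, t_half = log(2) / k,
                    integral = delta / k, k = k))
}

#' Simulate one individual's multi-sensor record with ground truth
#'
#' Lays out non-overlapping behavioral blocks (dive cycles, surface swims,
#' mud wallows, on-land hyperthermia excursions) on a 10-s grid, then
#' renders the four channels consistently: trapezoidal dive profiles and
#' shallow swim profiles on the depth channel; wet while at sea or in a
#' wallow; a diel light cycle attenuated exponentially with depth and
#' clamped to near-constant darkness in mud; and a stomach-temperature
#' baseline (warmer at sea) with sensor noise, slow drift, rectangular
#' hyperthermia excursions and instantaneous-drop exponential-recovery
#' ingestion events ([simulate_ingestion_curve()]). Every placed
#' perturbation is logged with its true parameters. Deterministic for a
#' fixed seed.
#'
#' @param cfg a [sim_config()].
#' @param seed integer RNG seed.
#' @param individual_id id stored in the series.
#' @return A list with `series` (a [sensor_series]) and `truth` (list of
#'   data.frames `events`, `ingestions`, `hyperthermia`).
#' @export
simulate_individual <- function(cfg = sim_config(), seed = 1,
                                individual_id = "sim01") {
  set.seed(seed)
  cad <- cfg$cadence
  n <- as.integer(round(cfg$duration_days * 86400 / cad))
  t0 <- as_utc(cfg$start_time)
  ts <- t0 + (seq_len(n) - 1L) * cad
  lead <- as.integer(cfg$lead_in_s / cad)
  margin <- as.integer(25 * 60 / cad)          # keeps separate blocks from chaining
  occupied <- logical(n)

  place <- function(len, pad = margin) {
    if (n - len - pad - lead < 1L) return(NA_integer_)
    for (try in seq_len(200L)) {
      i0 <- sample.int(n - len - pad - lead, 1L) + lead
      win <- max(1L, i0 - pad):min(n, i0 + len - 1L + pad)
      if (!any(occupied[win])) {
        occupied[i0:(i0 + len - 1L)] <<- TRUE
        return(i0)
      }
    }
    NA_integer_
  }

  ## ---- behavioral blocks -------------------------------------------------
  state <- integer(n)                           # 0 land, 1 wallow, 2 swim, 3 dive cycle
  depth <- numeric(n)
  ev_rows <- list()
  blocks <- list()                              # spans of at-sea blocks (for ingestion placement)

  ## dive cycles
  n_dives <- stats::rpois(1L, cfg$dive_rate * cfg$duration_days)
  sizes <- integer(0)
  while (sum(sizes) < n_dives)
    sizes <- c(sizes, 1L + stats::rgeom(1L, 1 / cfg$cycle_size_mean))
  if (length(sizes)) sizes[length(sizes)] <- sizes[length(sizes)] -
    (sum(sizes) - n_dives)
  sizes <- sizes[sizes > 0L]
  for (sz in sizes) {
    durs <- round(rtrunc(sz, stats::rlnorm, cfg$dive_dur_range[1],
                         cfg$dive_dur_range[2], meanlog = cfg$dive_dur_meanlog,
                         sdlog = cfg$dive_dur_sdlog) * 60 / cad)
    deps <- rtrunc(sz, stats::rlnorm, cfg$dive_depth_range[1],
                   cfg$dive_depth_range[2], meanlog = cfg$dive_depth_meanlog,
                   sdlog = cfg$dive_depth_sdlog)
    surfs <- if (sz > 1L) round(rtrunc(sz - 1L, stats::rlnorm,
                                       cfg$surface_range[1], cfg$surface_range[2],
                                       meanlog = cfg$surface_meanlog,
                                       sdlog = cfg$surface_sdlog) * 60 / cad)
    else integer(0)
    len <- sum(durs) + sum(surfs)
    i0 <- place(len)
    if (is.na(i0)) next
    state[i0:(i0 + len - 1L)] <- 3L
    pos <- i0
    for (j in seq_len(sz)) {
      d <- durs[j]
      prof <- dive_profile(d, deps[j])
      depth[pos:(pos + d - 1L)] <- prof
      ev_rows[[length(ev_rows) + 1L]] <- data.frame(
        kind = "dive", start_idx = pos, end_idx = pos + d - 1L,
        max_depth = max(prof), duration_s = d * cad)
      pos <- pos + d
      if (j < sz) {
        depth[pos:(pos + surfs[j] - 1L)] <- 0.05
        pos <- pos + surfs[j]
      }
    }
    blocks[[length(blocks) + 1L]] <- list(kind = "dive_cycle", i0 = i0,
                                          i1 = i0 + len - 1L)
  }

  ## surface swims
  n_swims <- stats::rpois(1L, cfg$swim_rate * cfg$duration_days)
  for (s in seq_len(n_swims)) {
    len <- as.integer(round(rtrunc(1L, stats::rlnorm, cfg$swim_dur_range[1],
                                   cfg$swim_dur_range[2],
                                   meanlog = cfg$swim_dur_meanlog,
                                   sdlog = cfg$swim_dur_sdlog) * 3600 / cad))
    i0 <- place(len)
    if (is.na(i0)) next
    d <- stats::runif(1L, cfg$swim_depth_range[1], cfg$swim_depth_range[2])
    prof <- flat_profile(len, d)
    state[i0:(i0 + len - 1L)] <- 2L
    depth[i0:(i0 + len - 1L)] <- prof
    ev_rows[[length(ev_rows) + 1L]] <- data.frame(
      kind = "surface_swim", start_idx = i0, end_idx = i0 + len - 1L,
      max_depth = max(prof), duration_s = len * cad)
    blocks[[length(blocks) + 1L]] <- list(kind = "swim", i0 = i0,
                                          i1 = i0 + len - 1L)
  }

  ## mud wallows
  n_wall <- stats::rpois(1L, cfg$wallow_rate * cfg$duration_days)
  for (w in seq_len(n_wall)) {
    len <- as.integer(round(stats::runif(1L, cfg$wallow_dur_range_min[1],
                                         cfg$wallow_dur_range_min[2]) * 60 / cad))
    i0 <- place(len)
    if (is.na(i0)) next
    d <- stats::runif(1L, cfg$wallow_depth_range[1], cfg$wallow_depth_range[2])
    prof <- flat_profile(len, d)
    state[i0:(i0 + len - 1L)] <- 1L
    depth[i0:(i0 + len - 1L)] <- prof
    ev_rows[[length(ev_rows) + 1L]] <- data.frame(
      kind = "wallow", start_idx = i0, end_idx = i0 + len - 1L,
      max_depth = max(prof), duration_s = len * cad)
  }

  ## hyperthermia excursions (on land, away from everything else)
  hyper_rows <- list()
  n_hyp <- stats::rpois(1L, cfg$hyper_rate * cfg$duration_days)
  for (h in seq_len(n_hyp)) {
    len <- as.integer(round(rtrunc(1L, stats::rnorm, 65, 240,
                                   mean = cfg$hyper_dur_mean_min,
                                   sd = cfg$hyper_dur_sd_min) * 60 / cad))
    i0 <- place(len, pad = as.integer(3600 / cad))
    if (is.na(i0)) next
    hyper_rows[[length(hyper_rows) + 1L]] <- data.frame(
      start_idx = i0, end_idx = i0 + len - 1L, duration_min = len * cad / 60,
      amp = cfg$hyper_amp)
  }
  hyper <- if (length(hyper_rows)) do.call(rbind, hyper_rows) else
    data.frame(start_idx = integer(0), end_idx = integer(0),
               duration_min = numeric(0), amp = numeric(0))

  events <- if (length(ev_rows)) do.call(rbind, ev_rows) else
    data.frame(kind = character(0), start_idx = integer(0),
               end_idx = integer(0), max_depth = numeric(0),
               duration_s = numeric(0))
  events <- events[order(events$start_idx), , drop = FALSE]
  rownames(events) <- NULL

  ## ---- stomach temperature ----------------------------------------------
  land_base <- stats::rnorm(1L, cfg$land_temp_mean, cfg$land_temp_sd)
  alpha <- 1 - exp(-cad / cfg$baseline_tau)
  target <- land_base + cfg$sea_offset * as.numeric(state >= 2L)
  base <- as.numeric(stats::filter(alpha * target, 1 - alpha,
                                   method = "recursive", init = target[1L]))
  base <- base + cfg$drift_per_10_days * (seq_len(n) - 1L) * cad / (10 * 86400)
  ## hyperthermia builds and decays by conduction over ~15 min, so the
  ## excursion is trapezoidal, not rectangular: its edges are far slower
  ## than an ingestion drop
  for (h in seq_len(nrow(hyper))) {
    span <- hyper$start_idx[h]:hyper$end_idx[h]
    len <- length(span)
    ramp <- min(as.integer(900 / cad), len %/% 4L)
    prof <- rep(hyper$amp[h], len)
    if (ramp > 0L) {
      prof[seq_len(ramp)] <- seq(0, hyper$amp[h], length.out = ramp)
      prof[(len - ramp + 1L):len] <- seq(hyper$amp[h], 0, length.out = ramp)
    }
    base[span] <- base[span] + prof
  }

  ## ingestion events
  ing_rows <- list()
  ing_busy <- logical(n)
  n_ing <- stats::rpois(1L, cfg$ingestion_rate * cfg$duration_days)
  hold <- as.integer(600 / cad)
  for (q in seq_len(n_ing)) {
    is_prey <- stats::runif(1L) < cfg$prey_prob
    k <- if (is_prey) stats::runif(1L, cfg$k_prey_range[1], cfg$k_prey_range[2])
    else stats::runif(1L, cfg$k_water_range[1], cfg$k_water_range[2])
    m <- stats::runif(1L, cfg$ingest_mass_range[1], cfg$ingest_mass_range[2])
    frac <- m / (cfg$stomach_mass + m)
    need <- as.integer(ceiling(log(frac * 30 / 0.15) / k / cad)) +
      hold + as.integer(900 / cad)
    ctx <- sample(names(cfg$context_probs), 1L, prob = cfg$context_probs)
    placedq <- FALSE
    for (try in seq_len(60L)) {
      i0 <- NA_integer_
      if (ctx == "diving") {
        dv <- events[events$kind == "dive", , drop = FALSE]
        if (!nrow(dv)) break
        r <- dv[sample.int(nrow(dv), 1L), ]
        cand <- r$start_idx + sample.int(max(1L, r$end_idx - r$start_idx), 1L)
        blk <- block_of(blocks, cand)
        ## leave the baseline 20 min to settle after entering the water,
        ## and room for the recovery to finish before hauling out
        if (!is.null(blk) && blk$i1 - cand >= need &&
            cand - blk$i0 >= 120L) i0 <- cand
      } else if (ctx == "surface_swimming") {
        sw <- Filter(function(b) b$kind == "swim", blocks)
        if (!length(sw)) break
        b <- sw[[sample.int(length(sw), 1L)]]
        room <- (b$i1 - need) - (b$i0 + 120L)
        if (room > 0L) i0 <- b$i0 + 120L + sample.int(room, 1L)
      } else {
        cand <- sample.int(n - need - lead, 1L) + lead
        win <- max(1L, cand - as.integer(1200 / cad)):(cand + need)
        if (!any(occupied[win])) i0 <- cand
      }
      if (!is.na(i0)) {
        win <- max(1L, i0 - as.integer(1200 / cad)):min(n, i0 + need)
        if (!any(ing_busy[win])) {
          ing_busy[max(1L, i0 - hold):min(n, i0 + need)] <- TRUE
          T1 <- base[i0]
          delta <- frac * (T1 - cfg$water_temp)
          len <- min(n - i0 + 1L,
                     as.integer(ceiling(log(delta / 0.005) / k / cad)) + 1L)
          tt <- (seq_len(len) - 1L) * cad
          base[i0:(i0 + len - 1L)] <- base[i0:(i0 + len - 1L)] -
            delta * exp(-k * tt)
          ing_rows[[length(ing_rows) + 1L]] <- data.frame(
            idx = i0, time = ts[i0], context = ctx,
            class = if (is_prey) "prey" else "water",
            m = m, k = k, T1 = T1, T2 = T1 - delta, delta_T = delta,
            t_half = log(2) / k, integral = delta / k,
            t_rec = log(delta / 0.3) / k)
          placedq <- TRUE
        }
      }
      if (placedq) break
    }
  }
  ingestions <- if (length(ing_rows)) do.call(rbind, ing_rows) else
    data.frame(idx = integer(0), time = as_utc(character(0)),
               context = character(0), class = character(0), m = numeric(0),
               k = numeric(0), T1 = numeric(0), T2 = numeric(0),
               delta_T = numeric(0), t_half = numeric(0),
               integral = numeric(0), t_rec = numeric(0))
  ingestions <- ingestions[order(ingestions$idx), , drop = FALSE]
  rownames(ingestions) <- NULL

  stomach <- base + stats::rnorm(n, 0, cfg$temp_noise_sd)

  ## ---- depth noise, light -----------------------------------------------
  wet <- state > 0L
  depth_noisy <- depth + stats::rnorm(n, 0, ifelse(wet, cfg$depth_noise_sd,
                                                   cfg$dry_depth_noise_sd))
  elev <- solar_elevation(ts, cfg$lat, cfg$lon)
  surface_light <- cfg$night_light +
    cfg$day_light_amp * pmax(0, sin(elev * pi / 180))
  light <- surface_light * exp(-cfg$light_attenuation * pmax(depth, 0)) +
    stats::rnorm(n, 0, 0.5)
  in_mud <- state == 1L
  light[in_mud] <- stats::runif(sum(in_mud), cfg$mud_light_range[1],
                                cfg$mud_light_range[2])
  light <- pmin(pmax(light, 0), 255)

  series <- sensor_series(ts, depth_noisy, light, wet, stomach,
                          individual_id = individual_id,
                          capture_time = t0, recapture_time = ts[n] + cad,
                          lat = cfg$lat, lon = cfg$lon)
  events$start <- ts[events$start_idx]
  events$end <- ts[events$end_idx] + cad
  hyper$start <- ts[hyper$start_idx]
  hyper$end <- ts[hyper$end_idx] + cad
  list(series = series,
       truth = list(events = events, ingestions = ingestions,
                    hyperthermia = hyper, land_base = land_base,
                    seed = seed))
}

## trapezoidal dive profile: 35% descent, 30% bottom, 35% ascent
dive_profile <- function(len, max_depth) {
  nd <- max(1L, round(0.35 * len)); na <- max(1L, round(0.35 * len))
  nb <- max(0L, len - nd - na)
  c(seq(0.6, max_depth, length.out = nd),
    rep(max_depth, nb),
    seq(max_depth, 0.6, length.out = na))[seq_len(len)]
}

## swim/wallow profile: short ramps in and out of a constant depth
flat_profile <- function(len, depth) {
  ramp <- min(6L, max(1L, len %/% 4L))
  mid <- max(0L, len - 2L * ramp)
  c(seq(0.6, depth, length.out = ramp), rep(depth, mid),
    seq(depth, 0.6, length.out = ramp))[seq_len(len)]
}

block_of <- function(blocks, idx) {
  for (b in blocks) if (idx >= b$i0 && idx <= b$i1) return(b)
  NULL
}

#' Simulate a cohort of individuals
#'
#' Per-individual seeds are derived from the master seed by a fixed affine
#' hash, so any individual can be regenerated independently.
#'
#' @param n number of individuals (>= 1).
#' @param cfg a [sim_config()] shared by all individuals.
#' @param master_seed integer master seed.
#' @return A list with named lists `series` and `truth` (one element per
#'   individual) and the integer vector `seeds`.
#' @export
simulate_cohort <- function(n, cfg = sim_config(), master_seed = 1) {
  stopifnot(n >= 1)
  seeds <- as.integer((as.numeric(master_seed) + 104729 * seq_len(n)) %%
                        2147483647)
  ids <- sprintf("sim%02d", seq_len(n))
  sims <- lapply(seq_len(n), function(i)
    simulate_individual(cfg, seed = seeds[i], individual_id = ids[i]))
  list(series = stats::setNames(lapply(sims, `[[`, "series"), ids),
       truth = stats::setNames(lapply(sims, `[[`, "truth"), ids),
       seeds = seeds)
}
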
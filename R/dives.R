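#' Detect and classify at-sea events
#'
#' Submerged phases are maximal runs with depth above the submersion
#' threshold (0.5 m) while the wet/dry sensor reads wet. Each phase is then
#' classified: phases whose light-level range is at most 5 instrument units
#' are mud-pool wallows (mud blocks light; sea water does not); remaining
#' phases are dives when the maximum depth exceeds 5 m, surface swimming
#' when it falls in \[1, 5\] m, and are discarded as splash below 1 m.
#' Consecutive surface-swimming phases separated by at most 20 min at the
#' surface are merged into a single surface-swim event.
#'
#' @param series a [sensor_series], depth zero-corrected
#'   ([zero_offset_correct()]); when `cfg$light_channel = "adjusted"` the
#'   series must carry a `light_adj` column ([remove_diel_light()]).
#' @param cfg a [dive_config()].
#' @return A data.frame of class `atsea_events`, one row per event:
#'   `event_id`, `kind` (`dive`/`surface_swim`/`wallow`), `start`, `end`
#'   (half-open, UTC), `duration_s`, `max_depth_m`, `time_to_max_s` (to the
#'   first attainment of maximum depth), `light_range`, `n_phases`
#'   (submerged sub-phases merged into the event), `surface_after_s` (gap
#'   to the next event, `NA` for the last), `start_idx`/`end_idx` (sample
#'   indices), and for dives the phase durations `descent_s`, `bottom_s`,
#'   `ascent_s`.
#' @export
detect_at_sea_events <- function(series, cfg = dive_config()) {
  lightch <- switch(cfg$light_channel,
                    raw = series$light,
                    adjusted = {
                      if (is.null(series$light_adj))
                        stopf("cfg$light_channel = 'adjusted' needs remove_diel_light() first")
                      series$light_adj
                    })
  cadence <- series_cadence(series)
  sub <- series$depth_m > cfg$submersion_depth & series$wet
  ph <- runs_true(sub)
  empty <- atsea_events_frame(attr(series, "individual_id"))
  if (!nrow(ph)) return(empty)

  ## per-phase metrics and provisional class
  ph$max_depth <- ph$time_to_max <- ph$light_range <- NA_real_
  ph$class <- NA_character_
  for (i in seq_len(nrow(ph))) {
    idx <- ph$start[i]:ph$end[i]
    dep <- series$depth_m[idx]
    imax <- which.max(dep)                       # first maximum on ties
    ph$max_depth[i] <- dep[imax]
    ph$time_to_max[i] <- (imax - 1L) * cadence
    lr <- range(lightch[idx], na.rm = TRUE)
    ph$light_range[i] <- lr[2] - lr[1]
    ph$class[i] <-
      if (ph$light_range[i] <= cfg$light_range_min) "wallow"
      else if (ph$max_depth[i] > cfg$dive_min_depth) "dive"
      else if (ph$max_depth[i] >= cfg$surface_swim_range[1]) "swim"
      else "splash"
  }
  ph <- ph[ph$class != "splash", , drop = FALSE]
  if (!nrow(ph)) return(empty)

  ## chain consecutive swim phases with surface gaps <= max_surface_gap
  ## (an intervening dive or wallow breaks the chain)
  ph$group <- seq_len(nrow(ph))
  for (i in seq_len(nrow(ph))[-1L]) {
    gap <- (ph$start[i] - ph$end[i - 1L] - 1L) * cadence
    if (ph$class[i] == "swim" && ph$class[i - 1L] == "swim" &&
        gap <= cfg$max_surface_gap)
      ph$group[i] <- ph$group[i - 1L]
  }

  groups <- split(seq_len(nrow(ph)), ph$group)
  ev <- do.call(rbind, lapply(groups, function(g) {
    i0 <- ph$start[g[1L]]; i1 <- ph$end[g[length(g)]]
    kind <- switch(ph$class[g[1L]], wallow = "wallow", dive = "dive",
                   swim = "surface_swim")
    idx <- i0:i1
    sub_idx <- unlist(lapply(g, function(k) ph$start[k]:ph$end[k]))
    dep <- series$depth_m
    dep_sub <- dep[sub_idx]
    imax <- sub_idx[which.max(dep_sub)]
    lr <- range(lightch[idx], na.rm = TRUE)
    data.frame(kind = kind,
               start_idx = i0, end_idx = i1,
               max_depth_m = max(dep_sub),
               time_to_max_s = (imax - i0) * cadence,
               light_range = lr[2] - lr[1],
               n_phases = length(g))
  }))
  ev <- ev[order(ev$start_idx), , drop = FALSE]
  ev$event_id <- seq_len(nrow(ev))
  ev$start <- series$timestamp[ev$start_idx]
  ev$end <- series$timestamp[ev$end_idx] + cadence
  ev$duration_s <- secs(ev$start, ev$end)
  ev$surface_after_s <- c(secs(ev$end[-nrow(ev)], ev$start[-1L]), NA_real_)

  ## dive phase segmentation
  ev$descent_s <- ev$bottom_s <- ev$ascent_s <- NA_real_
  for (i in which(ev$kind == "dive")) {
    p <- segment_dive_phases(series, ev[i, ])
    ev$descent_s[i] <- p$descent_s
    ev$bottom_s[i] <- p$bottom_s
    ev$ascent_s[i] <- p$ascent_s
  }
  rownames(ev) <- NULL
  ev <- ev[, c("event_id", "kind", "start", "end", "duration_s",
               "max_depth_m", "time_to_max_s", "light_range", "n_phases",
               "surface_after_s", "descent_s", "bottom_s", "ascent_s",
               "start_idx", "end_idx")]
  attr(ev, "individual_id") <- attr(series, "individual_id")
  class(ev) <- c("atsea_events", "data.frame")
  ev
}

atsea_events_frame <- function(id = NULL) {
  ev <- data.frame(event_id = integer(0), kind = character(0),
                   start = as_utc(character(0)), end = as_utc(character(0)),
                   duration_s = numeric(0), max_depth_m = numeric(0),
                   time_to_max_s = numeric(0), light_range = numeric(0),
                   n_phases = integer(0), surface_after_s = numeric(0),
                   descent_s = numeric(0), bottom_s = numeric(0),
                   ascent_s = numeric(0), start_idx = integer(0),
                   end_idx = integer(0))
  attr(ev, "individual_id") <- id
  class(ev) <- c("atsea_events", "data.frame")
  ev
}

#' Segment a dive into descent, bottom and ascent phases
#'
#' The descent runs from the dive start to the first attainment of the
#' bottom-phase depth (a configurable fraction, by default 80%, of the
#' maximum depth), the ascent from the last attainment to the dive end,
#' and the bottom phase lies between; the three phases partition the dive.
#' Ties for the maximum depth resolve to the earliest sample.
#'
#' @param series the [sensor_series] the dive was detected in.
#' @param event a single-row `atsea_events` slice with `kind == "dive"`.
#' @param cfg a [dive_config()].
#' @return A list with `descent_s`, `bottom_s`, `ascent_s`,
#'   `time_to_max_s`, and the phase boundary timestamps `descent_end` and
#'   `ascent_start`.
#' @export
segment_dive_phases <- function(series, event, cfg = dive_config()) {
  stopifnot(nrow(event) == 1L)
  cadence <- series_cadence(series)
  idx <- event$start_idx:event$end_idx
  dep <- series$depth_m[idx]
  thr <- cfg$bottom_fraction * max(dep)
  at <- which(dep >= thr)
  f <- at[1L]; l <- at[length(at)]
  t0 <- series$timestamp[idx[1L]]
  dur <- length(idx) * cadence
  descent_s <- (f - 1L) * cadence
  ascent_s <- dur - (l - 1L) * cadence
  list(descent_s = descent_s,
       bottom_s = dur - descent_s - ascent_s,
       ascent_s = ascent_s,
       time_to_max_s = (which.max(dep) - 1L) * cadence,
       descent_end = t0 + descent_s,
       ascent_start = t0 + (l - 1L) * cadence)
}

#' Group at-sea events into dive and surface-swim cycles
#'
#' Events of the same kind separated by less than the configured surface
#' gap (20 min, where observed surface-interval distributions break) are
#' chained into cycles; isolated events form singleton cycles. Wallows are
#' never grouped.
#'
#' @param events an `atsea_events` data.frame ([detect_at_sea_events()]).
#' @param cfg a [dive_config()].
#' @return A data.frame of class `event_cycles`: `cycle_id`, `kind`
#'   (`dive_cycle`/`swim_cycle`), `start`, `end`, `n_events`,
#'   `duration_s`, and a list-column `event_ids`.
#' @export
group_cycles <- function(events, cfg = dive_config()) {
  ev <- events[events$kind %in% c("dive", "surface_swim"), , drop = FALSE]
  out <- data.frame(cycle_id = integer(0), kind = character(0),
                    start = as_utc(character(0)), end = as_utc(character(0)),
                    n_events = integer(0), duration_s = numeric(0))
  out$event_ids <- list()
  if (nrow(ev)) {
    ev <- ev[order(ev$start), , drop = FALSE]
    rows <- list()
    for (kd in c("dive", "surface_swim")) {
      sub <- ev[ev$kind == kd, , drop = FALSE]
      if (!nrow(sub)) next
      grp <- cumsum(c(1L, as.integer(
        secs(sub$end[-nrow(sub)], sub$start[-1L]) >= cfg$max_surface_gap)))
      for (g in split(seq_len(nrow(sub)), grp)) {
        rows[[length(rows) + 1L]] <- data.frame(
          kind = if (kd == "dive") "dive_cycle" else "swim_cycle",
          start = sub$start[g[1L]], end = sub$end[g[length(g)]],
          n_events = length(g),
          duration_s = secs(sub$start[g[1L]], sub$end[g[length(g)]]),
          event_ids = I(list(sub$event_id[g])))
      }
    }
    out <- do.call(rbind, rows)
    out <- out[order(out$start), , drop = FALSE]
    out <- cbind(cycle_id = seq_len(nrow(out)), out)
    rownames(out) <- NULL
  }
  attr(out, "individual_id") <- attr(events, "individual_id")
  class(out) <- c("event_cycles", "data.frame")
  out
}

#' Per-individual behavior summary
#'
#' Descriptive diving metrics for one individual: estimated time at sea per
#' day, at-sea excursions (cycles) per day, dive and cycle counts, dives
#' per cycle, mean dive duration and depth, mean surface interval within
#' dive cycles, surface-swim counts and durations, and the fraction of
#' monitored days with at least one at-sea event.
#'
#' @param events an `atsea_events` data.frame.
#' @param cycles the matching `event_cycles` ([group_cycles()]).
#' @param monitored_days monitoring duration in days (> 0).
#' @param cfg a [dive_config()].
#' @return A one-row data.frame of class `behavior_summary`.
#' @export
summarize_behavior <- function(events, cycles, monitored_days,
                               cfg = dive_config()) {
  if (monitored_days <= 0) stopf("monitored_days must be > 0")
  dv <- events[events$kind == "dive", , drop = FALSE]
  sw <- events[events$kind == "surface_swim", , drop = FALSE]
  atsea <- events[events$kind %in% c("dive", "surface_swim"), , drop = FALSE]
  dc <- cycles[cycles$kind == "dive_cycle", , drop = FALSE]
  sc <- cycles[cycles$kind == "swim_cycle", , drop = FALSE]
  ## surface intervals after dives, within a cycle (gap below the chaining
  ## threshold)
  surf <- dv$surface_after_s[!is.na(dv$surface_after_s) &
                               dv$surface_after_s < cfg$max_surface_gap]
  days_with <- if (nrow(atsea)) {
    length(unique(format(atsea$start, "%Y-%m-%d")))
  } else 0L
  out <- data.frame(
    monitored_days = monitored_days,
    time_at_sea_per_day_min = sum(atsea$duration_s) / 60 / monitored_days,
    atsea_events_per_day = nrow(cycles) / monitored_days,
    n_dives = nrow(dv),
    n_dive_cycles = nrow(dc),
    dives_per_cycle = if (nrow(dc)) mean(dc$n_events) else NA_real_,
    n_surface_swims = nrow(sw),
    n_swim_cycles = nrow(sc),
    n_wallows = sum(events$kind == "wallow"),
    mean_dive_duration_min = if (nrow(dv)) mean(dv$duration_s) / 60 else NA_real_,
    mean_max_depth_m = if (nrow(dv)) mean(dv$max_depth_m) else NA_real_,
    mean_time_to_max_min = if (nrow(dv)) mean(dv$time_to_max_s) / 60 else NA_real_,
    mean_surface_min = if (length(surf)) mean(surf) / 60 else NA_real_,
    mean_swim_duration_h = if (nrow(sw)) mean(sw$duration_s) / 3600 else NA_real_,
    pct_days_with_atsea = 100 * min(days_with / monitored_days, 1))
  attr(out, "individual_id") <- attr(events, "individual_id")
  class(out) <- c("behavior_summary", "data.frame")
  out
}

#' @export
print.atsea_events <- function(x, ...) {
  cat(sprintf("<atsea_events> %d events (%d dives, %d surface swims, %d wallows)\n",
              nrow(x), sum(x$kind == "dive"), sum(x$kind == "surface_swim"),
              sum(x$kind == "wallow")))
  cols <- intersect(c("event_id", "kind", "start", "duration_s",
                      "max_depth_m", "light_range"), names(x))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x)[, cols], 10))
  invisible(x)
}
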
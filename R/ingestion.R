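## Stomach-temperature ingestion events.
##
## An ingestion shows as a sharp decline followed by a roughly exponential
## ("logarithmic") recovery. Anchors: T1 = last stable temperature before
## the drop, T2 = minimum (must be below 36.5 degC, the lowest core
## temperature described for elephant seals), T3 = first return to within
## baseline_tolerance of T1 sustained for >= 10 min.

#' Detect stomach-temperature ingestion events
#'
#' Each maximal run of samples below `cfg$t2_max` (36.5 degC) seeds a
#' candidate event at its minimum (T2, earliest sample on ties). T1 is
#' found scanning backward from T2 for the last sample whose local slope
#' magnitude (over `cfg$stable_window`) is below `cfg$stable_slope`; its
#' value is averaged over that stability window to suppress sensor noise.
#' T3 is the first sample after T2 from which the temperature stays at or
#' above T1 - `baseline_tolerance` for at least `baseline_hold`.
#' Candidates whose drop is smaller than `cfg$min_drop` are treated as
#' noise and dropped. Events are merged when a second drop begins before
#' the first recovery is complete or when the gap between them is below
#' `cfg$merge_gap` (double ingestions); the merged event keeps the global
#' minimum as T2. Implausible events (minimum below 20 degC, recovery
#' non-monotone by more than 1 degC after the last sub-minimum, or no
#' recovery before the record ends) are flagged `anomalous` and retained
#' for audit, never silently dropped.
#'
#' @param series a [sensor_series] whose stomach channel has been
#'   preprocessed ([preprocess()], [remove_outliers()]).
#' @param cfg an [ingest_config()].
#' @return A data.frame of class `ingestion_events` with anchor times and
#'   temperatures (`t_T1`, `t_T2`, `t_T3`, `T1`, `T2`, `T3`), sample
#'   indices, `merged_from`, `anomalous` and `anomaly_reason`. Feature
#'   columns are filled by [compute_event_features()].
#' @export
detect_ingestion_events <- function(series, cfg = ingest_config()) {
  x <- series$stomach_temp_c
  ts <- series$timestamp
  cadence <- series_cadence(series)
  empty <- ingestion_events_frame(attr(series, "individual_id"))
  if (all(is.na(x))) return(empty)

  rn <- runs_true(!is.na(x) & x < cfg$t2_max)
  if (!nrow(rn)) return(empty)

  w <- max(2L, as.integer(round(cfg$stable_window / cadence)))
  hold <- as.integer(ceiling(cfg$baseline_hold / cadence))
  lookback <- as.integer(6 * 3600 / cadence)

  cand <- list()
  for (i in seq_len(nrow(rn))) {
    seg <- rn$start[i]:rn$end[i]
    i2 <- seg[which.min(x[seg])]
    a <- anchor_T1(x, i2, w, cadence, cfg$stable_slope, lookback)
    if (is.null(a)) next
    if (a$T1 - x[i2] < cfg$min_drop) next       # indistinguishable from noise
    i3 <- find_T3(x, i2, a$T1, cfg$baseline_tolerance, hold)
    ## double ingestions can fall inside one sub-threshold excursion:
    ## count distinct descents of at least min_drop within the run
    sub <- count_drops(c(a$T1, x[seg]), cfg$min_drop)
    cand[[length(cand) + 1L]] <-
      list(i1 = a$i1, i2 = i2,
           i2_last = max(i2, rn$start[i] + sub$last_min_i - 2L),
           i3 = i3, T1 = a$T1,
           run_start = rn$start[i], merged_from = sub$count)
  }
  if (!length(cand)) return(empty)

  ## merge: second drop before first recovery, or near-adjacent drops
  merged <- list(cand[[1L]])
  for (k in seq_along(cand)[-1L]) {
    prev <- merged[[length(merged)]]
    cur <- cand[[k]]
    near <- if (!is.na(prev$i3)) {
      ## second drop before the first recovery, or nearly adjacent
      cur$run_start <= prev$i3 ||
        (cur$i1 - prev$i3) * cadence < cfg$merge_gap
    } else {
      ## recovery still pending: merge only close-by drops
      (cur$i1 - prev$i2_last) * cadence < cfg$merge_gap
    }
    if (near) {
      prev$merged_from <- prev$merged_from + cur$merged_from
      prev$i2_last <- cur$i2_last
      if (x[cur$i2] < x[prev$i2]) prev$i2 <- cur$i2
      prev$i3 <- find_T3(x, max(prev$i2, cur$i2), prev$T1,
                         cfg$baseline_tolerance, hold)
      merged[[length(merged)]] <- prev
    } else {
      merged[[length(merged) + 1L]] <- cur
    }
  }

  ev <- do.call(rbind, lapply(merged, function(e) {
    reason <- NA_character_
    if (x[e$i2] < 20) reason <- "minimum below 20 degC"
    else if (is.na(e$i3)) reason <- "no recovery before end of record"
    else if (nonmonotone_recovery(x, e$i2_last, e$i3))
      reason <- "non-monotone recovery"
    data.frame(i1 = e$i1, i2 = e$i2, i2_last = e$i2_last,
               i3 = e$i3 %||% NA_integer_,
               T1 = e$T1, T2 = x[e$i2],
               T3 = if (!is.na(e$i3 %||% NA)) x[e$i3] else NA_real_,
               merged_from = e$merged_from,
               anomalous = !is.na(reason), anomaly_reason = reason)
  }))
  ev$event_id <- seq_len(nrow(ev))
  ev$t_T1 <- ts[ev$i1]
  ev$t_T2 <- ts[ev$i2]
  ev$t_T3 <- ev$t_T2; ev$t_T3[] <- NA
  ok3 <- !is.na(ev$i3)
  ev$t_T3[ok3] <- ts[ev$i3[ok3]]
  for (col in c("delta_T", "T_half", "t_half_s", "index_I", "integral",
                "t_rec_s")) ev[[col]] <- NA_real_
  ev <- ev[, c("event_id", "t_T1", "t_T2", "t_T3", "T1", "T2", "T3",
               "delta_T", "T_half", "t_half_s", "index_I", "integral",
               "t_rec_s", "merged_from", "anomalous", "anomaly_reason",
               "i1", "i2", "i2_last", "i3")]
  attr(ev, "individual_id") <- attr(series, "individual_id")
  class(ev) <- c("ingestion_events", "data.frame")
  ev
}

ingestion_events_frame <- function(id = NULL) {
  ev <- data.frame(event_id = integer(0),
                   t_T1 = as_utc(character(0)), t_T2 = as_utc(character(0)),
                   t_T3 = as_utc(character(0)),
                   T1 = numeric(0), T2 = numeric(0), T3 = numeric(0),
                   delta_T = numeric(0), T_half = numeric(0),
                   t_half_s = numeric(0), index_I = numeric(0),
                   integral = numeric(0), t_rec_s = numeric(0),
                   merged_from = integer(0), anomalous = logical(0),
                   anomaly_reason = character(0),
                   i1 = integer(0), i2 = integer(0), i2_last = integer(0),
                   i3 = integer(0))
  attr(ev, "individual_id") <- id
  class(ev) <- c("ingestion_events", "data.frame")
  ev
}

## last stable sample before the drop; T1 averaged over the stability
## window to suppress single-sample noise
anchor_T1 <- function(x, i2, w, cadence, stable_slope, lookback) {
  lo <- max(w + 1L, i2 - lookback)
  if (i2 - 1L < lo) return(NULL)          # drop starts before any stable baseline
  for (j in seq(i2 - 1L, lo, by = -1L)) {
    if (is.na(x[j]) || is.na(x[j - w])) next
    slope <- (x[j] - x[j - w]) / (w * cadence)
    if (abs(slope) < stable_slope && x[j] > x[i2]) {
      win <- x[(j - w):j]
      return(list(i1 = j, T1 = mean(win, na.rm = TRUE)))
    }
  }
  NULL
}

## first sample after i2 from which temperature stays >= T1 - tol for
## >= hold samples (one-sided: overshooting the baseline still counts as
## recovered)
find_T3 <- function(x, i2, T1, tol, hold) {
  n <- length(x)
  if (i2 >= n) return(NA_integer_)
  tail_idx <- (i2 + 1L):n
  ok <- !is.na(x[tail_idx]) & x[tail_idx] >= T1 - tol
  rr <- runs_true(ok)
  rr <- rr[rr$end - rr$start + 1L >= hold, , drop = FALSE]
  if (!nrow(rr)) return(NA_integer_)
  tail_idx[rr$start[1L]]
}

## count distinct descents of >= min_drop in a temperature segment (the
## first element should be the pre-event baseline); a descent ends once
## the temperature has recovered half a min_drop above its bottom
count_drops <- function(xseg, min_drop) {
  runmax <- xseg[1L]; count <- 0L; last_min_i <- 1L
  bottom <- Inf; bottom_i <- 1L; in_descent <- FALSE
  for (i in seq_along(xseg)) {
    v <- xseg[i]
    if (is.na(v)) next
    if (v > runmax) runmax <- v
    if (!in_descent && runmax - v >= min_drop) in_descent <- TRUE
    if (in_descent) {
      if (v < bottom) { bottom <- v; bottom_i <- i }
      if (v >= bottom + min_drop / 2) {
        count <- count + 1L; last_min_i <- bottom_i
        runmax <- v; bottom <- Inf; in_descent <- FALSE
      }
    }
  }
  if (in_descent) { count <- count + 1L; last_min_i <- bottom_i }
  list(count = max(1L, count), last_min_i = last_min_i)
}

## recovery dipping > 1 degC below its running maximum marks the abrupt
## variations typical of pill measurement error
nonmonotone_recovery <- function(x, from, to, drop = 1.0) {
  if (is.na(to) || to - from < 2L) return(FALSE)
  seg <- x[from:to]
  seg <- seg[!is.na(seg)]
  any(cummax(seg) - seg > drop)
}

#' Compute quantitative features of an ingestion event
#'
#' Fills in the temperature drop `delta_T` = T1 - T2, the half-recovery
#' temperature `T_half` = T2 + delta_T/2, the half-recovery time `t_half`
#' (from the beginning of the decrease to the interpolated upward crossing
#' of `T_half`), the recovery-rate index `I = t_half / delta_T` (s/degC),
#' the recovery time `t_rec` = t(T3) - t(T2), and the area above the curve
#' (`integral`, s degC) by the trapezoid method.
#'
#' When the decline is unresolved at the sampling cadence (T2 follows T1 by
#' a single sample) the decrease is taken to begin at T2; otherwise at T1.
#' With the default `integral_method = "asymptote"` the area is measured
#' from the recovery asymptote (approximated by T1) and completed beyond
#' T3 with a nonparametric exponential tail (remaining deficit times
#' `t_half / ln 2`); `"truncated"` reproduces the plain truncated-at-T3
#' trapezoid against the T3 level.
#'
#' Events with `delta_T <= 0` or no recovery anchor are marked anomalous
#' and keep `NA` features.
#'
#' @param events an `ingestion_events` data.frame
#'   ([detect_ingestion_events()]).
#' @param series the [sensor_series] the events were detected in.
#' @param cfg an [ingest_config()].
#' @return The completed `ingestion_events` data.frame.
#' @export
compute_event_features <- function(events, series, cfg = ingest_config()) {
  if (!nrow(events)) return(events)
  x <- series$stomach_temp_c
  tnum <- as.numeric(series$timestamp)
  cadence <- series_cadence(series)
  for (r in seq_len(nrow(events))) {
    e <- events[r, ]
    if (is.na(e$i3)) next
    delta <- e$T1 - e$T2
    if (delta <= 0) {
      events$anomalous[r] <- TRUE
      events$anomaly_reason[r] <- "non-positive temperature drop"
      next
    }
    events$delta_T[r] <- delta
    events$T_half[r] <- e$T2 + delta / 2
    onset_idx <- if (e$i2 - e$i1 <= 1L) e$i2 else e$i1
    t_onset <- tnum[onset_idx]
    t_cross <- first_upcross(tnum, x, events$T_half[r], e$i2_last, e$i3)
    if (is.na(t_cross)) next
    events$t_half_s[r] <- t_cross - t_onset
    events$index_I[r] <- events$t_half_s[r] / delta
    events$t_rec_s[r] <- tnum[e$i3] - tnum[e$i2]
    idx <- onset_idx:e$i3
    idx <- idx[!is.na(x[idx])]          # trapezoid over available samples
    if (cfg$integral_method == "asymptote") {
      area <- trapz(tnum[idx], pmax(e$T1 - x[idx], 0))
      tail_deficit <- max(e$T1 - x[e$i3], 0)
      tau <- events$t_half_s[r] / log(2)
      events$integral[r] <- area + tail_deficit * tau
    } else {
      events$integral[r] <- trapz(tnum[idx], pmax(e$T3 - x[idx], 0))
    }
  }
  events
}

#' Classify ingestion events as water or prey by four published methods
#'
#' Four independent binary labels, one per published threshold: prey iff
#' index I > 250 s/degC; prey iff the area above the curve > 3000 s degC;
#' prey iff the recovery time > 35 min; prey iff the temperature drop
#' > 4.7 degC. Inequalities are strict: boundary values label water.
#' Anomalous events receive no labels.
#'
#' @param events a completed `ingestion_events` data.frame
#'   ([compute_event_features()]).
#' @param cfg an [ingest_config()].
#' @return `events` with character columns `label_I`, `label_integral`,
#'   `label_trec`, `label_dT` (`"prey"`/`"water"`, `NA` for anomalous
#'   events).
#' @export
classify_ingestion <- function(events, cfg = ingest_config()) {
  lab <- function(value, threshold) {
    out <- ifelse(value > threshold, "prey", "water")
    out[events$anomalous | is.na(value)] <- NA_character_
    out
  }
  events$label_I <- lab(events$index_I, cfg$i_threshold)
  events$label_integral <- lab(events$integral, cfg$integral_threshold)
  events$label_trec <- lab(events$t_rec_s, cfg$t_rec_threshold)
  events$label_dT <- lab(events$delta_T, cfg$delta_t_threshold)
  events
}

#' Detect on-land hyperthermia events
#'
#' The hyperthermia threshold is the `cfg$hyper_quantile` (97.5%) quantile
#' of the individual's on-land stomach temperatures, computed after
#' excluding samples inside detected ingestion events. Maximal on-land
#' runs strictly above the threshold lasting more than
#' `cfg$hyper_min_duration` (1 h) become events.
#'
#' @param series a [sensor_series].
#' @param land_mask logical vector, `TRUE` where the animal is on land;
#'   defaults to the complement of the wet sensor.
#' @param ingestions optional `ingestion_events`; their \[T1, T3\] spans
#'   are excluded from the quantile.
#' @param cfg an [ingest_config()].
#' @return A data.frame of class `hyperthermia_events`: `start`, `end`,
#'   `duration_min`, `mean_temp`, `threshold_used`.
#' @export
detect_hyperthermia <- function(series, land_mask = NULL, ingestions = NULL,
                                cfg = ingest_config()) {
  x <- series$stomach_temp_c
  cadence <- series_cadence(series)
  land <- land_mask %||% !series$wet
  land[is.na(land)] <- FALSE
  base <- land & !is.na(x)
  if (!is.null(ingestions) && nrow(ingestions)) {
    for (r in seq_len(nrow(ingestions))) {
      j3 <- ingestions$i3[r]
      if (is.na(j3)) j3 <- min(length(x), ingestions$i2[r] + 3600 %/% cadence)
      base[ingestions$i1[r]:j3] <- FALSE
    }
  }
  if (!any(base)) stopf("no on-land stomach temperature data")
  if (sum(base) * cadence < 24 * 3600)
    warnf("less than 24 h of on-land data; hyperthermia threshold is weakly determined")
  thr <- unname(stats::quantile(x[base], cfg$hyper_quantile, na.rm = TRUE))
  mask <- land & !is.na(x) & x > thr
  rr <- runs_true(mask)
  out <- data.frame(start = as_utc(character(0)), end = as_utc(character(0)),
                    duration_min = numeric(0), mean_temp = numeric(0),
                    threshold_used = numeric(0))
  if (nrow(rr)) {
    dur <- (rr$end - rr$start + 1L) * cadence
    keep <- dur > cfg$hyper_min_duration
    rr <- rr[keep, , drop = FALSE]
    if (nrow(rr)) {
      out <- data.frame(
        start = series$timestamp[rr$start],
        end = series$timestamp[rr$end] + cadence,
        duration_min = (rr$end - rr$start + 1L) * cadence / 60,
        mean_temp = vapply(seq_len(nrow(rr)), function(i)
          mean(x[rr$start[i]:rr$end[i]]), numeric(1)),
        threshold_used = thr)
    }
  }
  attr(out, "individual_id") <- attr(series, "individual_id")
  attr(out, "threshold") <- thr
  class(out) <- c("hyperthermia_events", "data.frame")
  out
}

#' @export
print.ingestion_events <- function(x, ...) {
  cat(sprintf("<ingestion_events> %d events (%d anomalous, %d merged doubles)\n",
              nrow(x), sum(x$anomalous), sum(x$merged_from > 1)))
  cols <- intersect(c("event_id", "t_T2", "T1", "T2", "delta_T", "index_I",
                      "integral", "t_rec_s", "anomalous"), names(x))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x)[, cols], 10))
  invisible(x)
}
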
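#' PCA swimming score
#'
#' A centered and scaled principal component analysis of three
#' per-individual metrics (number of dives, number of surface swims, mean
#' event duration) summarising how much time an individual spends in the
#' water. The sign indeterminacy is fixed so that a positive PC1 loading
#' on the number of dives means "higher PC1 = more diving"; on PC2 the
#' largest-magnitude loading is made positive.
#'
#' @param metrics data.frame with columns `individual_id`, `n_dives`,
#'   `n_surface_swims`, `mean_event_duration` (any consistent unit), one
#'   row per individual; at least 3 individuals, no zero-variance column.
#' @return An object of class `swimming_score`: list with `scores`
#'   (data.frame `individual_id`, `pc1`, `pc2`, `pc3`), `loadings`
#'   (variables x components), and `variance_explained` (proportions,
#'   non-increasing).
#' @export
swimming_score <- function(metrics) {
  need <- c("n_dives", "n_surface_swims", "mean_event_duration")
  miss <- setdiff(need, names(metrics))
  if (length(miss)) stopf("missing metric column(s): %s",
                          paste(miss, collapse = ", "))
  if (nrow(metrics) < 3L)
    stopf("swimming score needs at least 3 individuals, got %d", nrow(metrics))
  m <- as.matrix(metrics[, need])
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stopf("zero-variance column: %s", need[which(sds == 0)[1L]])
  p <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  rot <- p$rotation
  scores <- p$x
  ## sign conventions
  if (rot["n_dives", 1L] < 0) { rot[, 1L] <- -rot[, 1L]; scores[, 1L] <- -scores[, 1L] }
  if (ncol(rot) >= 2L) {
    j <- which.max(abs(rot[, 2L]))
    if (rot[j, 2L] < 0) { rot[, 2L] <- -rot[, 2L]; scores[, 2L] <- -scores[, 2L] }
  }
  ve <- p$sdev^2 / sum(p$sdev^2)
  out <- list(scores = data.frame(
    individual_id = metrics$individual_id %||% seq_len(nrow(metrics)),
    pc1 = scores[, 1L],
    pc2 = if (ncol(scores) >= 2L) scores[, 2L] else NA_real_,
    pc3 = if (ncol(scores) >= 3L) scores[, 3L] else NA_real_),
    loadings = rot, variance_explained = ve,
    center = p$center, scale = p$scale)
  class(out) <- "swimming_score"
  out
}

#' @export
print.swimming_score <- function(x, ...) {
  cat(sprintf("<swimming_score> %d individuals; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), 100 * x$variance_explained[1],
              100 * x$variance_explained[2]))
  print(round(x$loadings, 3))
  invisible(x)
}

#' Body condition metrics
#'
#' Body mass index (mass over length squared, kg/m^2), daily mass loss
#' over the monitoring period (kg/day) and specific daily mass loss per
#' unit initial body mass (g/kg/day).
#'
#' @param mass_start,mass_end body mass at capture and recapture, kg.
#' @param length body length, m.
#' @param monitoring_days days between the two weighings (> 0).
#' @param length_exponent exponent on length in the BMI (default 2).
#' @return A one-row data.frame of class `body_condition`: `bmi`,
#'   `daily_mass_loss`, `specific_mass_loss`.
#' @examples
#' body_condition(314.7, 294.5, 2.302, 6.3)
#' @export
body_condition <- function(mass_start, mass_end, length, monitoring_days,
                           length_exponent = 2) {
  stopifnot(mass_start > 0, mass_end > 0, length > 0)
  if (monitoring_days <= 0) stopf("monitoring_days must be > 0")
  loss <- (mass_start - mass_end) / monitoring_days
  out <- data.frame(bmi = mass_start / length^length_exponent,
                    daily_mass_loss = loss,
                    specific_mass_loss = loss / mass_start * 1000)
  class(out) <- c("body_condition", "data.frame")
  out
}

#' Cohort-level descriptive summary
#'
#' Aggregates per-individual event tables into the standard cohort
#' summaries: diving parameters as mean (sd) min-max rows (per-dive
#' metrics pooled over all dives, per-individual metrics over
#' individuals), prey counts and percentages for each of the four
#' ingestion classification methods, participation percentages (diving /
#' surface swimming / ingesting), and, when colony coordinates are given,
#' the percentage of events occurring in daytime.
#'
#' @param events named list (one element per individual) of
#'   `atsea_events`.
#' @param cycles matching named list of `event_cycles`.
#' @param ingestions matching named list of classified `ingestion_events`
#'   ([classify_ingestion()]); anomalous events are excluded from method
#'   counts.
#' @param monitored_days named numeric vector of monitoring durations.
#' @param lat,lon optional colony coordinates for the diel split.
#' @return An object of class `cohort_summary`: list with `diving`
#'   (data.frame metric/mean/sd/min/max), `ingestion_methods`,
#'   `participation`, `diel`, `n_individuals`, `n_events`.
#' @export
cohort_summary <- function(events, cycles, ingestions, monitored_days,
                           lat = NULL, lon = NULL) {
  n <- length(events)
  if (n == 0L) stopf("empty cohort")
  stopifnot(length(cycles) == n, length(ingestions) == n,
            length(monitored_days) == n)
  ids <- names(events) %||% as.character(seq_len(n))

  per <- do.call(rbind, lapply(seq_len(n), function(i) {
    s <- summarize_behavior(events[[i]], cycles[[i]], monitored_days[[i]])
    cbind(individual_id = ids[i], as.data.frame(s))
  }))
  all_dives <- do.call(rbind, lapply(events, function(e)
    as.data.frame(e)[e$kind == "dive", , drop = FALSE]))
  all_swims <- do.call(rbind, lapply(events, function(e)
    as.data.frame(e)[e$kind == "surface_swim", , drop = FALSE]))
  all_dc <- do.call(rbind, lapply(cycles, function(cc)
    as.data.frame(cc)[cc$kind == "dive_cycle", c("n_events", "duration_s")]))
  surf <- all_dives$surface_after_s
  surf <- surf[!is.na(surf) & surf < 20 * 60]

  msd <- function(x, scale = 1) {
    x <- x[!is.na(x)]
    if (!length(x)) return(c(NA_real_, NA_real_, NA_real_, NA_real_))
    c(mean(x), stats::sd(x), min(x), max(x)) / scale
  }
  rows <- rbind(
    time_at_sea_per_day_min = msd(per$time_at_sea_per_day_min),
    atsea_events_per_day = msd(per$atsea_events_per_day),
    dive_cycles_per_individual = msd(per$n_dive_cycles),
    dives_per_cycle = msd(all_dc$n_events),
    dives_per_individual = msd(per$n_dives),
    max_dive_depth_m = msd(all_dives$max_depth_m),
    dive_duration_min = msd(all_dives$duration_s, 60),
    time_at_surface_min = msd(surf, 60),
    surface_swim_duration_h = msd(all_swims$duration_s, 3600))
  diving <- data.frame(metric = rownames(rows), mean = rows[, 1],
                       sd = rows[, 2], min = rows[, 3], max = rows[, 4],
                       row.names = NULL)

  ing <- do.call(rbind, lapply(ingestions, function(x)
    as.data.frame(x)[!x$anomalous, , drop = FALSE]))
  n_events <- if (is.null(ing)) 0L else nrow(ing)
  method_row <- function(label, col) {
    k <- if (n_events) sum(ing[[col]] == "prey", na.rm = TRUE) else 0L
    data.frame(method = label, n_prey = k,
               pct_prey = if (n_events) 100 * k / n_events else NA_real_)
  }
  methods <- rbind(method_row("index_I", "label_I"),
                   method_row("integral", "label_integral"),
                   method_row("t_rec", "label_trec"),
                   method_row("delta_T", "label_dT"))

  participation <- data.frame(
    pct_diving = 100 * mean(per$n_dives > 0),
    pct_surface_swimming = 100 * mean(per$n_surface_swims > 0),
    pct_at_sea = 100 * mean(per$n_dives + per$n_surface_swims > 0),
    pct_ingesting = 100 * mean(vapply(ingestions, function(x)
      sum(!x$anomalous) > 0, logical(1))))

  diel <- NULL
  if (!is.null(lat) && !is.null(lon)) {
    pd <- function(tt) if (length(tt)) {
      100 * mean(day_night(tt, lat, lon) == "day")
    } else NA_real_
    diel <- data.frame(
      pct_dives_day = pd(all_dives$start),
      pct_swims_day = pd(all_swims$start),
      pct_ingestions_day = if (n_events) pd(ing$t_T2) else NA_real_)
  }

  out <- list(diving = diving, ingestion_methods = methods,
              participation = participation, diel = diel,
              per_individual = per,
              n_individuals = n, n_events = n_events)
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d individuals, %d ingestion events\n",
              x$n_individuals, x$n_events))
  cat("-- diving parameters (mean, sd, min, max) --\n")
  print(transform(x$diving, mean = round(mean, 2), sd = round(sd, 2),
                  min = round(min, 2), max = round(max, 2)))
  cat("-- ingestion classification --\n")
  print(transform(x$ingestion_methods, pct_prey = round(pct_prey, 1)))
  cat("-- participation (%) --\n")
  print(round(x$participation, 1))
  if (!is.null(x$diel)) {
    cat("-- daytime fraction (%) --\n")
    print(round(x$diel, 1))
  }
  invisible(x)
}
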
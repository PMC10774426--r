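#' Run the full per-individual analysis pipeline
#'
#' Chains the standard stages for one individual: post-capture trimming and
#' pill-loss truncation ([preprocess()]), stomach-channel outlier removal
#' ([remove_outliers()]), diel light adjustment when the record is long
#' enough ([remove_diel_light()]), at-sea event detection and cycle
#' grouping ([detect_at_sea_events()], [group_cycles()]), ingestion
#' detection, feature computation and four-method classification,
#' behavioral context assignment, hyperthermia detection with at-sea
#' latencies, drift assessment, and the per-individual behavior summary.
#'
#' @param series a [sensor_series] with `capture_time` metadata.
#' @param qc a [qc_config()].
#' @param dive a [dive_config()].
#' @param ingest an [ingest_config()].
#' @return A list of class `moltdive_analysis`: `series` (preprocessed),
#'   `events`, `cycles`, `ingestions`, `hyperthermia`, `drift`,
#'   `behavior`, `pill_loss_time`, `outliers_removed`.
#' @export
analyze_individual <- function(series, qc = qc_config(), dive = dive_config(),
                               ingest = ingest_config()) {
  pre <- preprocess(series, qc)
  s <- pre$series
  cadence <- series_cadence(s)
  outl <- integer(0)
  if (!all(is.na(s$stomach_temp_c))) {
    o <- remove_outliers(s$stomach_temp_c, qc, cadence)
    s$stomach_temp_c <- o$cleaned
    outl <- o$removed
  }
  s <- tryCatch(remove_diel_light(s, dive), error = function(e) {
    warnf("diel light adjustment skipped: %s", conditionMessage(e))
    s
  })
  events <- detect_at_sea_events(s, dive)
  cycles <- group_cycles(events, dive)
  ing <- detect_ingestion_events(s, ingest)
  ing <- compute_event_features(ing, s, ingest)
  ing <- classify_ingestion(ing, ingest)
  ing <- assign_context(ing, events, s)
  hyper <- tryCatch({
    h <- detect_hyperthermia(s, ingestions = ing, cfg = ingest)
    hyperthermia_latency(h, events)
  }, error = function(e) NULL)
  drift <- tryCatch(assess_drift(s$stomach_temp_c, qc, cadence),
                    error = function(e) NULL)
  days <- secs(s$timestamp[1L], s$timestamp[nrow(s)] + cadence) / 86400
  behavior <- summarize_behavior(events, cycles, days, dive)
  out <- list(series = s, events = events, cycles = cycles, ingestions = ing,
              hyperthermia = hyper, drift = drift, behavior = behavior,
              pill_loss_time = pre$pill_loss_time, outliers_removed = outl)
  class(out) <- "moltdive_analysis"
  out
}

#' @export
print.moltdive_analysis <- function(x, ...) {
  cat(sprintf("<moltdive_analysis> individual %s: %.1f monitored days\n",
              attr(x$series, "individual_id") %||% "?",
              x$behavior$monitored_days))
  cat(sprintf("  %d dives in %d cycles, %d surface swims, %d wallows\n",
              x$behavior$n_dives, x$behavior$n_dive_cycles,
              x$behavior$n_surface_swims, x$behavior$n_wallows))
  cat(sprintf("  %d ingestion events (%d anomalous), %d hyperthermia events\n",
              nrow(x$ingestions), sum(x$ingestions$anomalous),
              if (is.null(x$hyperthermia)) 0L else nrow(x$hyperthermia)))
  if (!is.null(x$drift))
    cat(sprintf("  stomach sensor drift: %+.3f degC / 10 days (tau %.2f)\n",
                x$drift$drift_per_10_days, x$drift$tau))
  invisible(x)
}
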
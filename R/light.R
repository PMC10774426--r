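#' Remove the diel cycle from the light channel
#'
#' Light-level variation must reflect depth (and mud), not the time of day,
#' before it can be used to discriminate behaviors. The day-night component
#' is estimated by classical seasonal decomposition based on moving
#' averages with a 24-h period and subtracted; the returned adjusted
#' channel is trend + residual, so event-scale drops are preserved.
#' The decomposition needs at least two full periods (48 h) of data;
#' shorter records are rejected.
#'
#' @param series a [sensor_series], or a plain numeric light vector (then
#'   `cadence` must be supplied).
#' @param cfg a [dive_config()].
#' @param cadence sample spacing in seconds; taken from the series when
#'   `series` is a `sensor_series`.
#' @return If given a `sensor_series`, the same series with an added
#'   `light_adj` column; if given a numeric vector, the adjusted vector.
#' @export
remove_diel_light <- function(series, cfg = dive_config(), cadence = NULL) {
  if (inherits(series, "sensor_series")) {
    adj <- remove_diel_light(series$light, cfg, series_cadence(series))
    series$light_adj <- adj
    return(series)
  }
  light <- as.numeric(series)
  if (is.null(cadence)) stopf("cadence required for a plain numeric channel")
  freq <- as.integer(round(cfg$diel_period / cadence))
  need <- as.integer(ceiling(cfg$min_record_for_decomposition / cadence))
  if (length(light) < max(need, 2L * freq))
    stopf("diel adjustment needs >= %g h of data, got %.1f h",
          cfg$min_record_for_decomposition / 3600,
          length(light) * cadence / 3600)
  filled <- light
  if (anyNA(filled)) {
    filled <- stats::approx(seq_along(light), light, seq_along(light),
                            rule = 2)$y
  }
  seasonal <- stats::decompose(stats::ts(filled, frequency = freq))$seasonal
  light - as.numeric(seasonal)
}
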
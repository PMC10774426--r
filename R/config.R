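#' Quality-control configuration
#'
#' Parameters governing pre-analysis quality control of stomach-temperature
#' records: the post-capture discard window (to exclude anesthesia effects),
#' the constant-reading rule used to detect loss of the stomach pill, the
#' rolling window of the outlier filter, the downsampling factor used for
#' drift assessment, and the pill's stated accuracy.
#'
#' @param post_capture_discard seconds of data discarded after capture
#'   (default 6 h).
#' @param pill_loss_constant_duration seconds of identical readings (at the
#'   0.1 degC instrument resolution) after which the pill is considered lost
#'   (default 3 h).
#' @param outlier_window width, in seconds, of the centered rolling window
#'   used by [remove_outliers()] (default 15 min).
#' @param downsample_factor integer subsampling factor applied before drift
#'   assessment (default 100, i.e. one sample per ~17 min at 10 s cadence).
#' @param stp_accuracy stated accuracy of the stomach temperature pill, degC.
#'   Deviations within this band are never flagged as outliers.
#' @param outlier_max_duration seconds; only excursions at most this long
#'   count as outliers. Genuine ingestion drops deviate from the rolling
#'   average for many minutes, while pill measurement errors are
#'   single-sample spikes; the run-length cap keeps the filter from eating
#'   real events.
#' @param resolution instrument resolution of the temperature channel, degC.
#' @return An object of class `qc_config` (a validated list).
#' @seealso [preprocess()], [remove_outliers()], [assess_drift()]
#' @export
qc_config <- function(post_capture_discard = 6 * 3600,
                      pill_loss_constant_duration = 3 * 3600,
                      outlier_window = 15 * 60,
                      downsample_factor = 100L,
                      stp_accuracy = 0.3,
                      outlier_max_duration = 30,
                      resolution = 0.1) {
  stopifnot(post_capture_discard > 0, pill_loss_constant_duration > 0,
            outlier_window > 0, downsample_factor >= 1, stp_accuracy >= 0,
            outlier_max_duration > 0, resolution > 0)
  structure(list(post_capture_discard = post_capture_discard,
                 pill_loss_constant_duration = pill_loss_constant_duration,
                 outlier_window = outlier_window,
                 downsample_factor = as.integer(downsample_factor),
                 stp_accuracy = stp_accuracy,
                 outlier_max_duration = outlier_max_duration,
                 resolution = resolution),
            class = "qc_config")
}

#' Dive-detection configuration
#'
#' Thresholds for submersion detection and behavioral classification.
#' Defaults follow the field protocol for molting southern elephant seals:
#' a submersion starts when depth exceeds 0.5 m with the wet/dry sensor
#' reading wet; surface swimming has a maximum depth between 1 and 5 m;
#' dives exceed 5 m; mud-pool wallows are recognized by a light-level range
#' of at most 5 instrument units over the event; events separated by less
#' than 20 min at the surface belong to the same cycle.
#'
#' @param submersion_depth depth threshold (m) starting a submerged phase.
#' @param surface_swim_range two-element numeric, the maximum-depth band (m)
#'   defining surface swimming.
#' @param dive_min_depth maximum depth (m) above which an event is a dive.
#' @param max_surface_gap seconds; surface intervals shorter than this merge
#'   swim sub-events and chain events into cycles.
#' @param light_range_min light range (instrument units) at or below which a
#'   submerged phase is classified as a mud wallow.
#' @param light_channel channel on which the wallow light range is measured:
#'   `"raw"` (default) or `"adjusted"` (diel-adjusted). Mud blocks light, so
#'   the raw channel is near-constant in a wallow regardless of time of day;
#'   the adjusted channel re-injects the subtracted diel pattern into
#'   optically isolated events and is kept only for comparison.
#' @param diel_period period (s) of the diel light cycle.
#' @param min_record_for_decomposition minimum record length (s) required by
#'   the seasonal decomposition of the light channel.
#' @param bottom_fraction fraction of maximum depth delimiting the bottom
#'   phase of a dive (descent ends at first attainment, ascent starts at
#'   last attainment).
#' @return An object of class `dive_config`.
#' @seealso [detect_at_sea_events()], [group_cycles()], [remove_diel_light()]
#' @export
dive_config <- function(submersion_depth = 0.5,
                        surface_swim_range = c(1, 5),
                        dive_min_depth = 5,
                        max_surface_gap = 20 * 60,
                        light_range_min = 5,
                        light_channel = c("raw", "adjusted"),
                        diel_period = 24 * 3600,
                        min_record_for_decomposition = 48 * 3600,
                        bottom_fraction = 0.8) {
  light_channel <- match.arg(light_channel)
  stopifnot(submersion_depth > 0, length(surface_swim_range) == 2L,
            surface_swim_range[1] < surface_swim_range[2],
            surface_swim_range[2] <= dive_min_depth,
            max_surface_gap > 0, light_range_min > 0,
            bottom_fraction > 0, bottom_fraction < 1)
  structure(list(submersion_depth = submersion_depth,
                 surface_swim_range = surface_swim_range,
                 dive_min_depth = dive_min_depth,
                 max_surface_gap = max_surface_gap,
                 light_range_min = light_range_min,
                 light_channel = light_channel,
                 diel_period = diel_period,
                 min_record_for_decomposition = min_record_for_decomposition,
                 bottom_fraction = bottom_fraction),
            class = "dive_config")
}

#' Ingestion-detection configuration
#'
#' Parameters for stomach-temperature ingestion-event detection, feature
#' computation, water-versus-prey classification, and on-land hyperthermia
#' detection. The four classification thresholds (recovery index I, area
#' above the curve, recovery time, temperature drop) are the published
#' values used to separate prey from water ingestion in pinnipeds.
#'
#' @param t2_max ceiling (degC) below which a local minimum can seed an
#'   event; the lowest core temperature described for elephant seals.
#' @param baseline_hold seconds the temperature must stay near baseline for
#'   the recovery anchor T3.
#' @param baseline_tolerance half-width (degC) of the "returned to baseline"
#'   band around T1; defaults to the pill accuracy.
#' @param merge_gap seconds; events closer than this are merged.
#' @param min_drop smallest temperature drop (degC) accepted as an event.
#'   Drops comparable to the pill accuracy cannot be distinguished from
#'   noise.
#' @param stable_slope slope magnitude (degC/s) below which the pre-drop
#'   temperature counts as stable when locating T1.
#' @param stable_window seconds over which the T1 stability slope is
#'   evaluated.
#' @param i_threshold prey iff index I strictly exceeds this (s/degC).
#' @param integral_threshold prey iff area above the curve strictly exceeds
#'   this (s degC).
#' @param t_rec_threshold prey iff recovery time strictly exceeds this (s).
#' @param delta_t_threshold prey iff temperature drop strictly exceeds this
#'   (degC).
#' @param integral_method `"asymptote"` (default): area above the curve
#'   measured from the recovery asymptote (taken as T1) with a
#'   nonparametric exponential tail completion beyond T3; `"truncated"`:
#'   area measured from T3 and truncated at T3.
#' @param hyper_quantile quantile of on-land temperatures defining the
#'   hyperthermia threshold.
#' @param hyper_min_duration seconds; excursions must exceed this to count
#'   as hyperthermia.
#' @return An object of class `ingest_config`.
#' @seealso [detect_ingestion_events()], [classify_ingestion()],
#'   [detect_hyperthermia()]
#' @export
ingest_config <- function(t2_max = 36.5,
                          baseline_hold = 10 * 60,
                          baseline_tolerance = 0.3,
                          merge_gap = 10 * 60,
                          min_drop = 0.5,
                          stable_slope = 0.005,
                          stable_window = 120,
                          i_threshold = 250,
                          integral_threshold = 3000,
                          t_rec_threshold = 35 * 60,
                          delta_t_threshold = 4.7,
                          integral_method = c("asymptote", "truncated"),
                          hyper_quantile = 0.975,
                          hyper_min_duration = 3600) {
  integral_method <- match.arg(integral_method)
  stopifnot(t2_max > 0, baseline_hold > 0, baseline_tolerance > 0,
            merge_gap >= 0, min_drop >= 0, stable_slope > 0,
            i_threshold > 0, integral_threshold > 0, t_rec_threshold > 0,
            delta_t_threshold > 0, hyper_quantile > 0, hyper_quantile < 1,
            hyper_min_duration > 0)
  structure(list(t2_max = t2_max, baseline_hold = baseline_hold,
                 baseline_tolerance = baseline_tolerance,
                 merge_gap = merge_gap, min_drop = min_drop,
                 stable_slope = stable_slope, stable_window = stable_window,
                 i_threshold = i_threshold,
                 integral_threshold = integral_threshold,
                 t_rec_threshold = t_rec_threshold,
                 delta_t_threshold = delta_t_threshold,
                 integral_method = integral_method,
                 hyper_quantile = hyper_quantile,
                 hyper_min_duration = hyper_min_duration),
            class = "ingest_config")
}
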
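#' Zero-offset depth correction
#'
#' Re-zeroes the depth channel using a known on-land (dry) interval, as done
#' at capture: the median depth over the interval is subtracted from the
#' whole channel, so the land median becomes 0. Applying the correction
#' twice with the same interval is a no-op.
#'
#' @param series a [sensor_series].
#' @param land_interval length-2 POSIXct (or parseable) vector, the
#'   half-open interval \[start, end) during which the animal was on land.
#' @return The corrected `sensor_series`, with the applied offset in
#'   attribute `"depth_offset"`.
#' @export
zero_offset_correct <- function(series, land_interval) {
  stopifnot(length(land_interval) == 2L)
  iv <- as_utc(land_interval)
  span <- range(series$timestamp)
  if (iv[1] < span[1] || iv[2] > span[2] + series_cadence(series) || iv[1] >= iv[2])
    stopf("land interval [%s, %s) outside the series span",
          format(iv[1]), format(iv[2]))
  inside <- series$timestamp >= iv[1] & series$timestamp < iv[2]
  if (!any(inside)) stopf("no samples inside the land interval")
  if (any(series$wet[inside], na.rm = TRUE))
    warnf("wet samples inside the supposed land interval (%d of %d)",
          sum(series$wet[inside], na.rm = TRUE), sum(inside))
  offset <- stats::median(series$depth_m[inside], na.rm = TRUE)
  series$depth_m <- series$depth_m - offset
  attr(series, "depth_offset") <- offset
  series
}

#' Rolling-average outlier filter for the stomach-temperature channel
#'
#' Deviations from a centered rolling average are screened with Tukey
#' fences (Q1 - 1.5 IQR, Q3 + 1.5 IQR) computed over the whole deployment.
#' Two refinements make the textbook recipe usable on pill data: (i) a
#' deviation is only an outlier if it also exceeds the pill's stated
#' accuracy, so samples inside the instrument's error band are never
#' removed; and (ii) the rolling baseline is re-fitted after masking, so a
#' gross spike does not drag its window neighbours outside the fences.
#' Flagged samples are set to `NA`, never interpolated.
#'
#' @param channel numeric temperature vector at fixed cadence.
#' @param cfg a [qc_config()].
#' @param cadence sample spacing in seconds (default 10).
#' @return A list with `cleaned` (the channel with outliers set `NA`),
#'   `removed` (integer indices), and `fences` (the final Tukey fences).
#' @export
remove_outliers <- function(channel, cfg = qc_config(), cadence = 10) {
  n <- length(channel)
  width <- as.integer(round(cfg$outlier_window / cadence))
  if (width %% 2L == 0L) width <- width + 1L
  if (width > n) stopf("outlier window (%d samples) longer than series (%d)",
                       width, n)
  x <- channel
  removed <- integer(0)
  fences <- c(NA_real_, NA_real_)
  for (it in seq_len(5L)) {
    base <- zoo::rollapply(zoo::zoo(x), width, mean, na.rm = TRUE,
                           partial = TRUE, align = "center")
    d <- channel - as.numeric(base)
    q <- stats::quantile(d, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
    iqr <- q[2] - q[1]
    fences <- c(q[1] - 1.5 * iqr, q[2] + 1.5 * iqr)
    ## candidates: outside the fences and beyond the instrument accuracy
    out_mask <- !is.na(d) & (d < fences[1] | d > fences[2]) &
      abs(d) > cfg$stp_accuracy
    ## sustained excursions (ingestion drops) are signal, not outliers:
    ## only short out-of-fence runs qualify
    max_run <- max(1L, as.integer(cfg$outlier_max_duration / cadence))
    rr <- runs_true(out_mask)
    rr <- rr[rr$end - rr$start + 1L <= max_run, , drop = FALSE]
    flag <- unlist(mapply(seq.int, rr$start, rr$end, SIMPLIFY = FALSE),
                   use.names = FALSE)
    flag <- setdiff(flag, removed)
    if (!length(flag)) break
    removed <- sort(c(removed, flag))
    x[removed] <- NA_real_
  }
  cleaned <- channel
  cleaned[removed] <- NA_real_
  list(cleaned = cleaned, removed = removed, fences = fences)
}

#' Assess stomach-temperature sensor drift
#'
#' Downsamples the temperature channel by `cfg$downsample_factor`, then
#' measures the monotone association between temperature and time with
#' Kendall's tau and estimates a robust linear trend as the median of
#' pairwise slopes (Theil-Sen). The slope is reported both per downsampled
#' step and rescaled to degC per 10 days. No correction is applied: drift
#' of the order of 0.1 degC per 10 days is below the pill accuracy over a
#' typical one-week deployment.
#'
#' @param channel numeric temperature vector at fixed cadence (`NA` allowed).
#' @param cfg a [qc_config()].
#' @param cadence sample spacing in seconds (default 10).
#' @return An object of class `drift_report`: list with `tau`, `slope`
#'   (degC per downsampled step), `drift_per_10_days` (degC),
#'   `correction_applied` (always `FALSE`), `n` (downsampled points used)
#'   and `step_s` (downsampled step, seconds).
#' @export
assess_drift <- function(channel, cfg = qc_config(), cadence = 10) {
  f <- cfg$downsample_factor
  ds <- channel[seq(1L, length(channel), by = f)]
  keep <- which(!is.na(ds))
  if (!length(keep)) stopf("temperature channel is entirely missing")
  step_s <- cadence * f
  if ((keep[length(keep)] - keep[1L]) * step_s < 48 * 3600)
    stopf("drift assessment needs at least 48 h of data after downsampling")
  x <- ds[keep]
  t <- as.numeric(keep)      # time in downsampled steps
  if (max(x) == min(x)) {
    tau <- 0; slope <- 0
  } else {
    tau <- suppressWarnings(stats::cor(t, x, method = "kendall"))
    dx <- outer(x, x, "-")
    dt <- outer(t, t, "-")
    slope <- stats::median(dx[dt > 0] / dt[dt > 0])
  }
  structure(list(tau = unname(tau), slope = slope,
                 drift_per_10_days = slope * (10 * 86400 / step_s),
                 correction_applied = FALSE,
                 n = length(x), step_s = step_s),
            class = "drift_report")
}

#' @export
print.drift_report <- function(x, ...) {
  cat(sprintf(paste0("<drift_report> Kendall tau = %.3f, Theil-Sen slope = ",
                     "%.3g degC/step (%gs steps, n = %d)\n"),
              x$tau, x$slope, x$step_s, x$n))
  cat(sprintf("  drift = %+.3f degC per 10 days; correction applied: %s\n",
              x$drift_per_10_days, x$correction_applied))
  invisible(x)
}

#' Trim a record after capture and truncate at pill loss
#'
#' Drops the first hours after capture (anesthesia effects) and truncates
#' the stomach-temperature channel at the start of the first run of
#' identical readings (at the instrument resolution) lasting at least the
#' configured duration, the signature of a lost / ejected pill.
#'
#' Depth, light and wet channels are only ever trimmed, never modified.
#'
#' @param series a [sensor_series] with `capture_time` metadata.
#' @param cfg a [qc_config()].
#' @return A list with `series` (trimmed) and `pill_loss_time` (POSIXct or
#'   `NULL` if the pill recorded to the end).
#' @export
preprocess <- function(series, cfg = qc_config()) {
  cap <- attr(series, "capture_time")
  if (is.null(cap)) stopf("capture_time metadata is required")
  start <- cap + cfg$post_capture_discard
  out <- series_window(series, from = start)
  if (nrow(out) == 0L)
    stopf("insufficient data: record ends within the %g h post-capture discard",
          cfg$post_capture_discard / 3600)
  pill_loss_time <- NULL
  stp <- out$stomach_temp_c
  if (!all(is.na(stp))) {
    cadence <- series_cadence(out)
    ## a run of k samples spans (k-1)*cadence seconds
    need <- as.integer(ceiling(cfg$pill_loss_constant_duration / cadence)) + 1L
    lev <- round(stp / cfg$resolution)
    lev[is.na(lev)] <- -Inf            # NA breaks constant runs
    r <- rle(lev)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    const <- which(r$lengths >= need & is.finite(r$values))
    if (length(const)) {
      i0 <- starts[const[1L]]
      pill_loss_time <- out$timestamp[i0]
      out$stomach_temp_c[i0:nrow(out)] <- NA_real_
    }
  }
  list(series = out, pill_loss_time = pill_loss_time)
}
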
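test_that("no events are found without a sub-36.5 minimum", {
  s <- make_series(2000, stomach = 37.0)
  expect_equal(nrow(detect_ingestion_events(s)), 0L)
  s2 <- make_series(2000, stomach = NA_real_)
  expect_equal(nrow(detect_ingestion_events(s2)), 0L)
})

test_that("a single clean drop is anchored at T1, T2 and T3", {
  n <- 3000
  x <- exp_drop_channel(n, 800, T1 = 37, delta = 4, k = 1 / 600)
  s <- make_series(n, stomach = x)
  ev <- detect_ingestion_events(s)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$T1, 37, tolerance = 1e-6)
  expect_equal(ev$T2, 33)
  expect_equal(ev$i2, 800L)
  ## T3: first sustained return to within 0.3 degC of T1, i.e. when the
  ## deficit falls below 0.3: t = ln(4/0.3)/k
  t3_expected <- 800 + ceiling(log(4 / 0.3) * 600 / 10)
  expect_lte(abs(ev$i3 - t3_expected), 1)
  expect_false(ev$anomalous)
})

test_that("features match the exponential-recovery closed forms", {
  ## T(t) = T1 - delta exp(-kt): t_half = ln2/k, I = t_half/delta,
  ## area above the asymptote = delta/k
  for (delta in c(2, 5)) {
    for (k in c(1 / 600, 1 / 1500)) {
      n <- as.integer(log(delta / 0.002) / k / 10) + 600
      x <- exp_drop_channel(n, 400, T1 = 37, delta = delta, k = k)
      s <- make_series(n, stomach = x)
      ev <- compute_event_features(detect_ingestion_events(s), s)
      expect_equal(ev$delta_T, delta, tolerance = 1e-6)
      expect_equal(ev$T_half, 37 - delta / 2, tolerance = 1e-6)
      expect_equal(ev$t_half_s, log(2) / k, tolerance = 0.02)
      expect_equal(ev$index_I, log(2) / k / delta, tolerance = 0.02)
      expect_equal(ev$integral, delta / k, tolerance = 0.02)
    }
  }
})

test_that("midpoint and index formulas hold at the published boundary", {
  ## T1 = 37, T2 = 32 -> T_half = 34.5; t_half = 1000 s with delta = 4
  ## sits exactly at the 250 s/degC boundary
  n <- 3000
  x <- exp_drop_channel(n, 500, T1 = 37, delta = 5, k = 1 / 600)
  s <- make_series(n, stomach = x)
  ev <- compute_event_features(detect_ingestion_events(s), s)
  expect_equal(ev$T_half, 34.5, tolerance = 1e-6)
  expect_equal(1000 / 4, 250)              # the index is t_half over delta
})

test_that("the truncated-at-T3 integral variant converges to delta/k", {
  cfg <- ingest_config(integral_method = "truncated",
                       baseline_tolerance = 0.02)
  k <- 1 / 600; delta <- 5
  n <- as.integer(log(delta / 0.002) / k / 10) + 600
  x <- exp_drop_channel(n, 400, T1 = 37, delta = delta, k = k)
  s <- make_series(n, stomach = x)
  ev <- compute_event_features(detect_ingestion_events(s, cfg), s, cfg)
  expect_equal(ev$integral, delta / k, tolerance = 0.05)
})

test_that("double drops before recovery merge into one event", {
  n <- 4000
  x <- rep(37, n)
  ## first drop at sample 800, second 5 min later, before recovery
  t1 <- (0:(n - 800)) * 10
  x[800:n] <- 37 - 3 * exp(-t1 / 600)
  i2 <- 830                                 # 5 min after the first
  t2 <- (0:(n - i2)) * 10
  x[i2:n] <- x[i2:n] - 2.5 * exp(-t2 / 600)
  s <- make_series(n, stomach = x)
  ev <- detect_ingestion_events(s)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$merged_from, 2L)
  ## the global minimum is kept as T2
  expect_equal(ev$T2, min(x, na.rm = TRUE))
})

test_that("implausible events are flagged anomalous, not dropped", {
  n <- 3000
  ## minimum below 20 degC (pill ejected / gross error)
  x <- exp_drop_channel(n, 800, T1 = 37, delta = 19, k = 1 / 400)
  s <- make_series(n, stomach = x)
  ev <- detect_ingestion_events(s)
  expect_equal(nrow(ev), 1L)
  expect_true(ev$anomalous)
  expect_match(ev$anomaly_reason, "20 degC")
  ## anomalous events receive no classification labels
  ev <- classify_ingestion(compute_event_features(ev, s))
  expect_true(is.na(ev$label_I))

  ## censored recovery: record ends before return to baseline
  x2 <- exp_drop_channel(1200, 1100, T1 = 37, delta = 4, k = 1 / 600)
  ev2 <- detect_ingestion_events(make_series(1200, stomach = x2))
  expect_true(ev2$anomalous)
  expect_match(ev2$anomaly_reason, "no recovery")
})

test_that("classification thresholds are strict on all four methods", {
  base <- data.frame(event_id = 1:3,
                     index_I = c(250, 250.1, 200),
                     integral = c(3000, 3000.5, 100),
                     t_rec_s = c(35 * 60, 35 * 60 + 10, 30 * 60),
                     delta_T = c(4.7, 4.8, 2),
                     anomalous = FALSE)
  lab <- classify_ingestion(base)
  expect_equal(lab$label_I, c("water", "prey", "water"))
  expect_equal(lab$label_integral, c("water", "prey", "water"))
  expect_equal(lab$label_trec, c("water", "prey", "water"))
  expect_equal(lab$label_dT, c("water", "prey", "water"))
})

test_that("larger drops at fixed recovery rate never shrink the integral", {
  k <- 1 / 600
  last <- -Inf
  for (delta in c(1, 2, 3, 4.5, 6)) {
    n <- as.integer(log(delta / 0.002) / k / 10) + 600
    x <- exp_drop_channel(n, 400, T1 = 37, delta = delta, k = k)
    s <- make_series(n, stomach = x)
    ev <- compute_event_features(detect_ingestion_events(s), s)
    expect_gt(ev$integral, last)
    last <- ev$integral
  }
})

test_that("hyperthermia detection applies the quantile-and-duration rule", {
  set.seed(4)
  n <- 5 * 8640                             # five days on land
  x <- rnorm(n, 36.6, 0.05)
  ## +1.5 degC excursion of 110 min, and one of 30 min
  a0 <- 10000; a1 <- a0 + 660 - 1
  b0 <- 30000; b1 <- b0 + 180 - 1
  x[a0:a1] <- x[a0:a1] + 1.5
  x[b0:b1] <- x[b0:b1] + 1.5
  s <- make_series(n, stomach = x, wet = FALSE)
  h <- detect_hyperthermia(s)
  expect_equal(nrow(h), 1L)
  expect_equal(h$duration_min, 110, tolerance = 1 / 660)
  expect_equal(h$start, s$timestamp[a0])
  expect_gt(h$mean_temp, attr(h, "threshold"))

  ## a globally rising baseline with no sustained excursion above its own
  ## 97.5% quantile: top 2.5% of a 36 h ramp lasts 54 min < 1 h
  n2 <- 36 * 360
  ramp <- 36.3 + seq(0, 1, length.out = n2)
  s2 <- make_series(n2, stomach = ramp, wet = FALSE)
  expect_equal(nrow(suppressWarnings(detect_hyperthermia(s2))), 0L)
})

test_that("ingestion drops are excluded from the hyperthermia baseline", {
  set.seed(9)
  n <- 3 * 8640
  x <- rnorm(n, 36.6, 0.05)
  x2 <- exp_drop_channel(n, 9000, T1 = 36.6, delta = 4, k = 1 / 600)
  x <- x + (x2 - 36.6)
  s <- make_series(n, stomach = x, wet = FALSE)
  ing <- detect_ingestion_events(s)
  h_with <- detect_hyperthermia(s, ingestions = ing)
  thr_with <- attr(h_with, "threshold")
  thr_wout <- attr(detect_hyperthermia(s), "threshold")
  ## excluding the drop interval cannot raise the quantile above the
  ## all-data value by more than rounding, and both stay near baseline
  expect_lt(abs(thr_with - (36.6 + qnorm(0.975) * 0.05)), 0.05)
  expect_lte(thr_wout, thr_with + 1e-9)
})
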
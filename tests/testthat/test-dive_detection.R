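test_that("diel light removal keeps event-scale structure", {
  n <- 8640 * 2                            # 48 h
  tt <- seq_len(n)
  diel <- 100 + 80 * sin(2 * pi * tt / 8640)
  adj <- remove_diel_light(diel, cadence = 10)
  ## pure 24 h signal: residual variation under 1% of the amplitude
  expect_lt(diff(range(adj)), 0.01 * 160)

  ## a 30-min step drop of 50 units survives the adjustment
  stepped <- diel
  drop_idx <- 4000:4180
  stepped[drop_idx] <- stepped[drop_idx] - 50
  adj2 <- remove_diel_light(stepped, cadence = 10)
  recovered <- mean(adj2[setdiff(3500:4500, drop_idx)]) - mean(adj2[drop_idx])
  expect_lt(abs(recovered - 50), 5)

  ## 40 h is too short for the decomposition
  expect_error(remove_diel_light(diel[1:(40 * 360)], cadence = 10), "48")
})

test_that("submerged phases classify as dive, wallow, swim or splash", {
  n <- 8640
  depth <- rep(0, n); wet <- rep(FALSE, n); light <- rep(100, n)
  ## a 12 m dive with varying light
  depth[1000:1060] <- c(seq(1, 12, length.out = 20), rep(12, 21),
                        seq(12, 1, length.out = 20))
  wet[995:1065] <- TRUE
  light[1000:1060] <- 100 - 40 * depth[1000:1060] / 12
  ## a shallow mud wallow: wet, 3 m, near-constant light
  depth[3000:3180] <- 3
  wet[3000:3180] <- TRUE
  light[3000:3180] <- 3
  ## a surface swim at 2 m with light variation
  depth[5000:5600] <- 2
  wet[5000:5600] <- TRUE
  light[5000:5600] <- 70 + seq(0, 15, length.out = 601)
  ## a sub-metre splash with light variation
  depth[7000:7010] <- 0.8
  wet[7000:7010] <- TRUE
  light[7000:7010] <- seq(100, 60, length.out = 11)

  s <- make_series(n, depth = depth, light = light, wet = wet)
  ev <- detect_at_sea_events(s)
  expect_equal(ev$kind, c("dive", "wallow", "surface_swim"))
  expect_equal(ev$max_depth_m, c(12, 3, 2))
  expect_true(ev$light_range[2] <= 5)
  expect_true(all(ev$light_range[c(1, 3)] > 5))
})

test_that("dry records and sub-threshold noise yield no events", {
  set.seed(2)
  s <- make_series(8640, depth = rnorm(8640, 0, 0.1), wet = FALSE)
  expect_equal(nrow(detect_at_sea_events(s)), 0L)
  ## wet but shallow noise below the 0.5 m threshold
  s2 <- make_series(8640, depth = rnorm(8640, 0, 0.15), wet = TRUE)
  expect_equal(sum(detect_at_sea_events(s2)$kind %in%
                     c("dive", "surface_swim")), 0L)
})

test_that("swim sub-phases merge across short surface gaps only", {
  n <- 8640
  depth <- rep(0, n); wet <- rep(FALSE, n)
  light <- rep(80, n)
  ## two 2 m submerged phases separated by 10 min at the surface
  depth[1000:1300] <- 2; depth[1361:1600] <- 2
  wet[1000:1600] <- TRUE
  light[1000:1300] <- seq(60, 90, length.out = 301)
  light[1361:1600] <- seq(60, 90, length.out = 240)
  ## a third phase 25 min after the second
  depth[1751:1900] <- 2
  wet[1751:1900] <- TRUE
  light[1751:1900] <- seq(60, 90, length.out = 150)
  s <- make_series(n, depth = depth, light = light, wet = wet)
  ev <- detect_at_sea_events(s)
  sw <- ev[ev$kind == "surface_swim", ]
  expect_equal(nrow(sw), 2L)
  expect_equal(sw$n_phases, c(2L, 1L))
})

test_that("phase segmentation follows the 80% bottom rule", {
  n <- 2000
  ## symmetric V dive: 3 min down, 3 min up to 20 m
  depth <- rep(0, n); wet <- rep(FALSE, n); light <- rep(100, n)
  vprof <- c(seq(1, 20, length.out = 18), seq(20, 1, length.out = 18))
  depth[301:336] <- vprof
  wet[301:336] <- TRUE
  light[301:336] <- 100 - 3 * vprof
  s <- make_series(n, depth = depth, light = light, wet = wet)
  ev <- detect_at_sea_events(s)
  expect_equal(ev$kind, "dive")
  expect_equal(ev$time_to_max_s, 170)      # first attainment of the maximum
  ## V shape: bottom spans the 80%-of-max band on both limbs
  vthr <- 0.8 * max(vprof)
  expect_equal(ev$bottom_s,
               10 * (rev(which(vprof >= vthr))[1] - which(vprof >= vthr)[1]))

  ## trapezoid: 2 min down, 4 min at 10 m, 2 min up; the 80% rule puts
  ## the descent/ascent boundaries at 8 m, crossed 20% before/after the
  ## plateau
  depth2 <- rep(0, n); wet2 <- rep(FALSE, n)
  prof <- c(seq(10 / 12, 10, length.out = 12), rep(10, 24),
            seq(10, 10 / 12, length.out = 12))
  depth2[501:548] <- prof
  wet2[501:548] <- TRUE
  light2 <- rep(100, n); light2[501:548] <- 100 - 3 * prof
  s2 <- make_series(n, depth = depth2, light = light2, wet = wet2)
  ev2 <- detect_at_sea_events(s2)
  ## expected boundaries from the constructed profile itself
  thr <- 0.8 * max(prof)
  first80 <- which(prof >= thr)[1]
  last80 <- rev(which(prof >= thr))[1]
  expect_equal(ev2$descent_s, (first80 - 1) * 10)
  expect_equal(ev2$bottom_s, (last80 - first80) * 10)
  expect_equal(ev2$descent_s + ev2$bottom_s + ev2$ascent_s, ev2$duration_s)

  ## double maximum: time to max goes to the first
  depth3 <- rep(0, n); wet3 <- rep(FALSE, n)
  prof3 <- c(seq(1, 15, length.out = 10), seq(15, 9, length.out = 6),
             seq(9, 15, length.out = 6), seq(15, 1, length.out = 10))
  depth3[701:732] <- prof3
  wet3[701:732] <- TRUE
  light3 <- rep(100, n); light3[701:732] <- 100 - 3 * prof3
  ev3 <- detect_at_sea_events(make_series(n, depth = depth3, light = light3,
                                          wet = wet3))
  expect_equal(ev3$time_to_max_s, (which.max(prof3) - 1) * 10)
})

test_that("cycle grouping chains events separated by under 20 min", {
  ## 19 min gap: one cycle of two
  ev <- make_events(c("dive", "dive"), c(0, 600 + 19 * 60), c(600, 600),
                    c(10, 12))
  cyc <- group_cycles(ev)
  expect_equal(nrow(cyc), 1L)
  expect_equal(cyc$n_events, 2L)

  ## 21 min gap: two singleton cycles
  ev <- make_events(c("dive", "dive"), c(0, 600 + 21 * 60), c(600, 600),
                    c(10, 12))
  cyc <- group_cycles(ev)
  expect_equal(cyc$n_events, c(1L, 1L))

  ## gaps 5, 30, 10 min: cycles of sizes 2 and 2
  starts <- c(0, 600 + 5 * 60, 1200 + 35 * 60, 1800 + 45 * 60)
  ev <- make_events(rep("dive", 4), starts, rep(600, 4), rep(10, 4))
  cyc <- group_cycles(ev)
  expect_equal(cyc$n_events, c(2L, 2L))
  ## cycle members cover the event set exactly
  expect_setequal(unlist(cyc$event_ids), ev$event_id)

  ## wallows are never grouped
  ev <- make_events(c("wallow", "wallow"), c(0, 1200), c(600, 600), c(1, 1))
  expect_equal(nrow(group_cycles(ev)), 0L)
})

test_that("behavior summary aggregates events and cycles", {
  expect_error(summarize_behavior(make_events(character(0), numeric(0),
                                              numeric(0), numeric(0)),
                                  group_cycles(make_events(character(0),
                                                           numeric(0),
                                                           numeric(0),
                                                           numeric(0))),
                                  0), "monitored_days")
  ## empty record
  ev0 <- make_events(character(0), numeric(0), numeric(0), numeric(0))
  s0 <- summarize_behavior(ev0, group_cycles(ev0), 7)
  expect_equal(s0$n_dives, 0L)
  expect_equal(s0$time_at_sea_per_day_min, 0)
  expect_equal(s0$pct_days_with_atsea, 0)

  ## three dives of 6, 8, 10 minutes
  ev <- make_events(rep("dive", 3), c(0, 3600, 7200), c(360, 480, 600),
                    c(8, 10, 12))
  s1 <- summarize_behavior(ev, group_cycles(ev), 2)
  expect_equal(s1$mean_dive_duration_min, 8)
  expect_equal(s1$n_dives, 3L)
  expect_equal(s1$time_at_sea_per_day_min, (360 + 480 + 600) / 60 / 2)
})

test_that("classification is stable under small depth offsets", {
  sim <- simulate_individual(sim_config(duration_days = 3), seed = 31)
  ev1 <- detect_at_sea_events(sim$series)
  shifted <- sim$series
  shifted$depth_m <- shifted$depth_m + 0.04
  ev2 <- detect_at_sea_events(shifted)
  expect_equal(ev2$kind, ev1$kind)
})

test_that("detection recovers simulated events with their true classes", {
  sim <- simulate_individual(sim_config(), seed = 13)
  ev <- detect_at_sea_events(sim$series)
  cyc <- group_cycles(ev)
  tr <- sim$truth$events
  m <- match_events(tr, ev)
  expect_true(all(!is.na(m)))
  expect_equal(ev$kind[m], tr$kind)
  ## no extra detections
  expect_equal(nrow(ev), nrow(tr))
  ## per-dive metrics agree with truth
  dv <- tr$kind == "dive"
  expect_lt(max(abs(ev$max_depth_m[m][dv] - tr$max_depth[dv])), 0.25)
  expect_lt(max(abs(ev$duration_s[m][dv] - tr$duration_s[dv])), 30)
  ## reconstructed summary counts match the truth log exactly
  days <- nrow(sim$series) * 10 / 86400
  sm <- summarize_behavior(ev, cyc, days)
  expect_equal(sm$n_dives, sum(dv))
  expect_equal(sm$n_surface_swims, sum(tr$kind == "surface_swim"))
  expect_equal(sm$n_wallows, sum(tr$kind == "wallow"))
  expect_equal(sm$mean_dive_duration_min,
               mean(tr$duration_s[dv]) / 60, tolerance = 0.05)
})
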
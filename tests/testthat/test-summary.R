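test_that("swimming score ranks a dominant individual first on PC1", {
  m <- data.frame(individual_id = c("a", "b", "c", "d"),
                  n_dives = c(2, 3, 2.5, 25),
                  n_surface_swims = c(1, 2, 1.5, 15),
                  mean_event_duration = c(5, 6, 5.5, 50))
  sc <- swimming_score(m)
  expect_equal(which.max(sc$scores$pc1), 4L)
  ## PC1 loading on the number of dives is positive by convention
  expect_gt(sc$loadings["n_dives", 1], 0)
  ## variance shares are non-increasing and sum to 1
  expect_true(all(diff(sc$variance_explained) <= 1e-12))
  expect_equal(sum(sc$variance_explained), 1)
})

test_that("identical individuals score identically; the mean scores zero", {
  m <- data.frame(individual_id = c("a", "b", "c"),
                  n_dives = c(1, 3, 2),
                  n_surface_swims = c(2, 4, 3),
                  mean_event_duration = c(3, 5, 4))
  ## individual c sits exactly at the column means
  sc <- swimming_score(m)
  expect_equal(unlist(sc$scores[3, c("pc1", "pc2", "pc3")]),
               c(pc1 = 0, pc2 = 0, pc3 = 0), tolerance = 1e-12)

  m2 <- data.frame(individual_id = c("a", "b", "c", "d"),
                   n_dives = c(5, 5, 1, 9),
                   n_surface_swims = c(2, 2, 1, 4),
                   mean_event_duration = c(7, 7, 2, 11))
  sc2 <- swimming_score(m2)
  expect_equal(sc2$scores$pc1[1], sc2$scores$pc1[2])
  expect_equal(sc2$scores$pc2[1], sc2$scores$pc2[2])
})

test_that("swimming score validates its input", {
  m <- data.frame(individual_id = c("a", "b"),
                  n_dives = 1:2, n_surface_swims = 1:2,
                  mean_event_duration = 1:2)
  expect_error(swimming_score(m), "3 individuals")
  m3 <- data.frame(individual_id = c("a", "b", "c"),
                   n_dives = c(1, 1, 1), n_surface_swims = 1:3,
                   mean_event_duration = 1:3)
  expect_error(swimming_score(m3), "n_dives")
})

test_that("scores and loadings reconstruct the scaled matrix", {
  set.seed(3)
  m <- data.frame(individual_id = letters[1:8],
                  n_dives = rpois(8, 20),
                  n_surface_swims = rpois(8, 10),
                  mean_event_duration = runif(8, 3, 30))
  sc <- swimming_score(m)
  z <- scale(as.matrix(m[, 2:4]))
  recon <- as.matrix(sc$scores[, c("pc1", "pc2", "pc3")]) %*% t(sc$loadings)
  expect_equal(unname(recon), unname(z[, ]), tolerance = 1e-10)
})

test_that("body condition arithmetic", {
  b <- body_condition(314.7, 294.5, 2.302, 6.3)
  expect_equal(b$bmi, 314.7 / 2.302^2)
  expect_equal(round(b$bmi, 1), 59.4)
  expect_equal(body_condition(100, 79.8, 2, 6.3)$daily_mass_loss,
               20.2 / 6.3)
  expect_equal(body_condition(100, 100, 2, 5)$daily_mass_loss, 0)
  expect_error(body_condition(100, 90, 2, 0), "monitoring_days")
  ## configurable length exponent
  expect_equal(body_condition(100, 90, 2, 5, length_exponent = 3)$bmi,
               100 / 8)
})

test_that("cohort summary mirrors the published table structure", {
  ## one individual, one dive: min = max = mean
  ev <- make_events("dive", 0, 480, 12)
  cyc <- group_cycles(ev)
  ing0 <- moltdive:::ingestion_events_frame("a")
  cs <- cohort_summary(list(a = ev), list(a = cyc), list(a = ing0),
                       c(a = 7))
  row <- cs$diving[cs$diving$metric == "dive_duration_min", ]
  expect_equal(row$mean, 8)
  expect_equal(row$min, 8)
  expect_equal(row$max, 8)
  expect_equal(cs$participation$pct_diving, 100)
  expect_equal(cs$participation$pct_ingesting, 0)

  expect_error(cohort_summary(list(), list(), list(), numeric(0)), "empty")
})

test_that("method counts follow the strict-threshold row logic", {
  ## 87 events, 46 with t_rec above 35 min -> 46 (53%)
  set.seed(11)
  n <- 87
  ing <- data.frame(event_id = seq_len(n),
                    t_T2 = T0 + seq_len(n) * 3600,
                    anomalous = FALSE,
                    index_I = c(rep(300, 39), rep(100, 48)),
                    integral = c(rep(4000, 25), rep(1000, 62)),
                    t_rec_s = c(rep(40 * 60, 46), rep(20 * 60, 41)),
                    delta_T = c(rep(5, 22), rep(2, 65)))
  ing <- classify_ingestion(ing)
  ev0 <- make_events(character(0), numeric(0), numeric(0), numeric(0))
  cs <- cohort_summary(list(a = ev0), list(a = group_cycles(ev0)),
                       list(a = ing), c(a = 7))
  mm <- cs$ingestion_methods
  expect_equal(mm$n_prey[mm$method == "index_I"], 39)
  expect_equal(mm$n_prey[mm$method == "integral"], 25)
  expect_equal(mm$n_prey[mm$method == "t_rec"], 46)
  expect_equal(mm$n_prey[mm$method == "delta_T"], 22)
  expect_equal(mm$pct_prey[mm$method == "t_rec"], 100 * 46 / 87)
  expect_equal(round(mm$pct_prey[mm$method == "t_rec"]), 53)
})

test_that("cohort summary is invariant to individual order", {
  sim <- simulate_cohort(3, sim_config(duration_days = 3), master_seed = 2)
  parts <- lapply(sim$series, function(s) {
    ev <- detect_at_sea_events(s)
    ing <- classify_ingestion(compute_event_features(
      detect_ingestion_events(s), s))
    list(ev = ev, cyc = group_cycles(ev), ing = ing)
  })
  days <- setNames(rep(3, 3), names(parts))
  fwd <- cohort_summary(lapply(parts, `[[`, "ev"),
                        lapply(parts, `[[`, "cyc"),
                        lapply(parts, `[[`, "ing"), days)
  rev_ <- cohort_summary(lapply(rev(parts), `[[`, "ev"),
                         lapply(rev(parts), `[[`, "cyc"),
                         lapply(rev(parts), `[[`, "ing"), rev(days))
  expect_equal(fwd$diving, rev_$diving)
  expect_equal(fwd$ingestion_methods, rev_$ingestion_methods)
  expect_equal(fwd$participation, rev_$participation)
})
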
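test_that("noise-free fixes lie exactly on the true path and runs repeat", {
  cfg <- sim_config(n_birds = 1, seed = 13, outlier_rate = 0,
                    class_error_sd_m = c("3" = 1e-9, "2" = 1e-9, "1" = 1e-9,
                                         "0" = 1e-9, "A" = 1e-9, "B" = 1e-9),
                    heavy_tail_prob = 0)
  s <- simulate_track(cfg, 1)
  # project fixes and true path; each fix must sit on the segment between
  # its day's true position and the next (or at the colony on shore days)
  xy <- aeqd_project(cbind(s$fixes$lon, s$fixes$lat), cfg$colony)
  path <- s$truth$path
  day <- match(as.Date(s$fixes$time, tz = "UTC"), path$date)
  off <- vapply(seq_len(nrow(xy)), function(i) {
    a <- c(path$x_km[day[i]], path$y_km[day[i]])
    b <- if (day[i] < nrow(path))
      c(path$x_km[day[i] + 1], path$y_km[day[i] + 1]) else a
    # distance from point to segment a-b (also covers sortie days, whose
    # fixes run along a ray from the colony)
    p <- xy[i, ]
    ab <- b - a
    t <- if (sum(ab^2) == 0) 0 else
      max(0, min(1, sum((p - a) * ab) / sum(ab^2)))
    sqrt(sum((p - (a + t * ab))^2))
  }, numeric(1))
  # at-sea days: exactly on the daily segments; shore days: at the nest
  n_pre <- 2 + 2 * cfg$pre_departure_trips
  expect_close(off[day > n_pre], 0, 1e-6)
  expect_close(off[day <= 2], 0, 1e-6)

  s2 <- simulate_track(cfg, 1)
  expect_identical(s$fixes, s2$fixes)  # bit-reproducible under the seed
})

test_that("the class-noise model has the configured scale and mix", {
  # pure class-B noise, heavy tail off: per-axis displacement sd within
  # 10% of the configured 10 km (Monte-Carlo against the stated model)
  cfg <- sim_config(n_birds = 1, seed = 17, outlier_rate = 0,
                    fixes_per_day = c(8, 8),
                    class_mix = c("3" = 0, "2" = 0, "1" = 0, "0" = 0,
                                  "A" = 0, "B" = 1),
                    heavy_tail_prob = 0)
  s <- simulate_track(cfg, 1)
  expect_true(all(s$fixes$lc == "B"))
  xy <- aeqd_project(cbind(s$fixes$lon, s$fixes$lat), cfg$colony)
  path <- s$truth$path
  day <- match(as.Date(s$fixes$time, tz = "UTC"), path$date)
  secs <- as.numeric(s$fixes$time) %% 86400
  frac <- secs / 86400
  nxtx <- c(path$x_km[-1], path$x_km[nrow(path)])
  nxty <- c(path$y_km[-1], path$y_km[nrow(path)])
  truex <- path$x_km[day] + frac * (nxtx[day] - path$x_km[day])
  truey <- path$y_km[day] + frac * (nxty[day] - path$y_km[day])
  transit <- day > 6  # skip shore/sortie days where truth is the nest
  ex <- xy[transit, 1] - truex[transit]
  ey <- xy[transit, 2] - truey[transit]
  n <- sum(transit)
  expect_gt(n, 300)
  expect_close(stats::sd(c(ex, ey)), 10, 1)

  # class mix converges at n = 1e4 (binomial tolerance, 4 sd)
  cfg2 <- sim_config(n_birds = 1, seed = 19, fixes_per_day = c(8, 8))
  fx <- dplyr::bind_rows(lapply(1:15, function(b)
    simulate_track(cfg2, b)$fixes))
  fx <- fx[seq_len(min(10000, nrow(fx))), ]
  p_ab <- mean(fx$lc %in% c("A", "B"))
  expect_close(p_ab, 0.49, 4 * sqrt(0.49 * 0.51 / nrow(fx)))
})

test_that("outbound travel matches the drawn daily rate within 15%", {
  cfg <- sim_config(n_birds = 20, seed = 23,
                    status_probs = c(complete = 1, inbound_incomplete = 0,
                                     outward_incomplete = 0))
  for (b in 1:20) {
    s <- simulate_track(cfg, b)
    path <- s$truth$path
    out <- path$date > s$truth$departure_date &
      path$date < s$truth$loiter_start
    d <- sqrt(diff(path$x_km[out])^2 + diff(path$y_km[out])^2)
    expect_close(mean(d), s$truth$mean_daily_km,
                 0.15 * s$truth$mean_daily_km)
  }
})

test_that("cohorts honour censoring proportions and truth contracts", {
  cfg <- sim_config(n_birds = 17, seed = 29)
  co <- cached_cohort("c17", cfg)
  expect_equal(as.integer(table(co$statuses)[c("complete",
                                               "inbound_incomplete",
                                               "outward_incomplete")]),
               c(5L, 4L, 8L))
  for (tr in co$truth) {
    if (tr$status == "complete") {
      expect_false(is.na(tr$landfall_date))
      expect_true(tr$reversal_date >= tr$loiter_start &&
                  tr$reversal_date <= tr$loiter_end)
    }
    if (tr$status == "outward_incomplete") expect_true(is.na(tr$reversal_date))
    # truth indices reference existing fixes
    expect_true(all(range(as.Date(co$fixes$time[co$fixes$bird_id ==
      tr$bird_id], tz = "UTC")) == range(tr$path$date)))
  }
  expect_equal(nrow(simulate_cohort(sim_config(n_birds = 0))$fixes), 0)
})

test_that("synthetic environmental stacks have the stated structure", {
  g <- grid_spec(nx = 100, ny = 100)  # ~1e4 cells
  env <- simulate_env(g, seed = 31, coupling = FALSE)
  st <- env$stack
  expect_setequal(names(st$layers),
                  c("BATHY", "SLOPE", "SST", "CHLA", "CURR", "SLA", "MLD"))

  # uncoupled source layers are mutually uncorrelated (SLOPE and CURR
  # are deterministic derivatives of BATHY and SLA and are exempt)
  src <- c("BATHY", "SST", "CHLA", "SLA", "MLD")
  L <- sapply(st$layers[src], as.numeric)
  L <- L[stats::complete.cases(L), ]
  r <- stats::cor(L); diag(r) <- 0
  expect_lt(max(abs(r)), 0.2)

  g2 <- grid_spec(nx = 40, ny = 40)
  # eddy amplitude 0 -> flat SLA -> identically zero current speed
  env0 <- simulate_env(g2, seed = 31, eddy_amplitude_m = 0)
  expect_true(all(env0$stack$layers$CURR == 0))

  # constant-field override
  envc <- simulate_env(g2, seed = 31, constant = list(SST = 12))
  expect_true(all(envc$stack$layers$SST == 12))

  # coupling raises CHLA along the first front
  envc2 <- simulate_env(g, seed = 31, coupling = TRUE)
  expect_gt(mean(envc2$stack$layers$CHLA), mean(env$stack$layers$CHLA))
})
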
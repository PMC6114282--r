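# Brute-force RMS speed oracle, independent of the filter internals:
# speeds (m/s) from fix i to its up-to-two neighbours each side.
oracle_rms <- function(fixes, i, idx = seq_len(nrow(fixes))) {
  pos <- match(i, idx)
  nb <- idx[pos + c(-2, -1, 1, 2)]
  nb <- nb[!is.na(nb)]
  v <- sapply(nb, function(j) {
    d <- great_circle_km(c(fixes$lon[i], fixes$lat[i]),
                         c(fixes$lon[j], fixes$lat[j])) * 1000
    d / abs(as.numeric(fixes$time[j]) - as.numeric(fixes$time[i]))
  })
  sqrt(mean(v^2))
}

line_track <- function(n = 10, speed_ms = 1, dt_s = 3600) {
  # eastward along the equator at `speed_ms`
  step_deg <- speed_ms * dt_s / 1000 / 111.3195
  tibble::tibble(bird_id = "L",
                 time = as.POSIXct("2016-12-01", tz = "UTC") +
                   (seq_len(n) - 1) * dt_s,
                 lon = (seq_len(n) - 1) * step_deg, lat = 0,
                 lc = "1")
}

test_that("speed stage removes exactly the displaced fix on a clean line", {
  fx <- line_track(10)
  fx$lat[5] <- 50 / 111.3195  # displaced ~50 km off the line
  # oracle: only fix 5 (and fixes having 5 as neighbour) can exceed vmax,
  # and fix 5 has the largest RMS
  rms <- sapply(2:9, function(i) oracle_rms(fx, i))
  expect_true(which.max(rms) + 1 == 5)
  expect_gt(max(rms), 2)
  res <- sda_filter(fx, filter_config())
  expect_equal(res$removed$time, fx$time[5])
  expect_equal(res$removed$reason, "speed")
  expect_equal(nrow(res$retained), 9)
})

test_that("short tracks and benign geometry pass untouched", {
  fx <- line_track(2)
  res <- sda_filter(fx)
  expect_equal(nrow(res$retained), 2)

  # equilateral zigzag: 60-degree interior angles, 1 km steps -> the
  # spike thresholds (15/25 degrees) never fire, speeds are slow
  n <- 12
  xy <- matrix(0, n, 2)
  for (i in 2:n)
    xy[i, ] <- xy[i - 1, ] + c(0.5, ifelse(i %% 2 == 0, 0.866, -0.866))
  ll <- aeqd_unproject(xy, c(168, -44))
  fx <- tibble::tibble(bird_id = "Z",
                       time = as.POSIXct("2016-12-01", tz = "UTC") +
                         (seq_len(n) - 1) * 3600,
                       lon = ll[, 1], lat = ll[, 2], lc = "1")
  res <- sda_filter(fx)
  expect_equal(nrow(res$removed), 0)

  expect_error(sda_filter(fx[c(3, 1, 2), ]), "sorted")
})

test_that("class-Z fixes are dropped and tagged", {
  fx <- line_track(6)
  fx$lc[3] <- "Z"
  res <- sda_filter(fx)
  expect_equal(res$removed$reason, "class_z")
  expect_equal(nrow(res$retained), 5)
  res2 <- sda_filter(fx, filter_config(drop_class_z = FALSE))
  expect_equal(nrow(res2$retained), 6)
})

test_that("turning angle follows the bearing geometry", {
  # collinear equatorial points heading east: straight continuation
  expect_equal(turning_angle(c(0, 0), c(1, 0), c(2, 0)), 180,
               tolerance = 1e-9)
  # out-and-back: full reversal
  expect_equal(turning_angle(c(0, 0), c(1, 0), c(0, 0)), 0, tolerance = 1e-9)
  # right-angle corner at small local scale
  ctr <- c(168, -44)
  p <- aeqd_unproject(rbind(c(0, 0), c(1, 0), c(1, 1)), ctr)
  expect_equal(turning_angle(p[1, ], p[2, ], p[3, ]), 90, tolerance = 0.1)
  # coincident points: defined as 180 (no spike)
  expect_equal(turning_angle(c(1, 0), c(1, 0), c(2, 0)), 180)
})

test_that("spike stage removes acute out-and-back fixes by the dual rule", {
  # a 20-degree spike with 10 km legs at slow speed (below vmax)
  xy <- rbind(c(0, 0), c(5, 0), c(10, 0),
              c(15 - 10 * cos(20 * pi / 180), 10 * sin(20 * pi / 180)),
              c(15, 0), c(20, 0), c(25, 0))
  ll <- aeqd_unproject(xy, c(168, -44))
  fx <- tibble::tibble(bird_id = "S",
                       time = as.POSIXct("2016-12-01", tz = "UTC") +
                         (seq_len(nrow(xy)) - 1) * 3 * 3600,
                       lon = ll[, 1], lat = ll[, 2], lc = "1")
  res <- sda_filter(fx)
  expect_true("spike" %in% res$removed$reason)
  # the same geometry with 2 km legs is under both distance thresholds
  xy2 <- xy * 0.2
  ll2 <- aeqd_unproject(xy2, c(168, -44))
  fx2 <- fx; fx2$lon <- ll2[, 1]; fx2$lat <- ll2[, 2]
  expect_equal(nrow(sda_filter(fx2)$removed), 0)
})

test_that("filtering is idempotent and leaves no RMS violation behind", {
  cfg <- sim_config(n_birds = 2, seed = 21, outlier_rate = 0.05)
  for (b in 1:2) {
    fx <- simulate_track(cfg, b)$fixes
    res <- sda_filter(fx)
    kept <- res$retained
    # re-scan: every retained non-endpoint fix obeys the RMS criterion
    idx <- seq_len(nrow(kept))
    if (nrow(kept) >= 3) {
      rms <- sapply(idx[-c(1, length(idx))], function(i)
        oracle_rms(kept, i, idx))
      expect_true(all(rms <= 2 + 1e-12))
    }
    # idempotence: a second pass removes nothing
    res2 <- sda_filter(kept)
    expect_equal(nrow(res2$removed), 0)
    # partition: retained + removed = input
    expect_equal(nrow(res$retained) + nrow(res$removed), nrow(fx))
  }
})
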
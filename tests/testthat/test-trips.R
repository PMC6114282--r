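# Brute-force run enumeration for the departure rule.
oracle_departure <- function(dates, dist, thresh = 20, min_days = 3) {
  away <- dist > thresh
  r <- rle(away)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  cand <- which(r$values &
                as.numeric(dates[ends] - dates[starts]) + 1 >= min_days)
  if (!length(cand)) return(as.Date(NA))
  dates[starts[max(cand)]]
}

test_that("final departure skips pre-departure sorties", {
  # away from day 1
  d <- make_daily(pre = 0, out = 10)
  expect_equal(detect_final_departure(d), d$date[2])  # first day > 20 km

  # two 2-day coastal sorties, then permanent leave on day 9
  ctr <- c(168.188, -44.188)
  xy <- rbind(c(0.5, 0), c(25, -25), c(28, -22), c(0.5, 0),
              c(-20, 25), c(-22, 28), c(0.5, 0), c(0.5, 0))
  for (i in 1:10) xy <- rbind(xy, i * 60 * c(sin(4), cos(4)))
  ll <- aeqd_unproject(xy, ctr)
  dates <- as.Date("2016-11-20") + seq_len(nrow(xy)) - 1
  d <- tibble::tibble(bird_id = "P", date = dates,
                      mean_time = as.POSIXct(paste(dates, "12:00:00"),
                                             tz = "UTC"),
                      lon = ll[, 1], lat = ll[, 2], n_fixes = 1L)
  dep <- detect_final_departure(d)
  expect_equal(dep, dates[9])
  cd <- great_circle_km(cbind(d$lon, d$lat),
                        matrix(ctr, nrow(d), 2, byrow = TRUE))
  expect_equal(dep, oracle_departure(dates, cd))

  # never leaves -> error
  d0 <- d[c(1, 4, 7, 8), ]
  expect_error(detect_final_departure(d0), "no departure")
})

test_that("reversal is the earliest maximum-distance day", {
  d <- make_daily(out = 12, inbound = TRUE)
  dep <- detect_final_departure(d)
  trip <- d[d$date >= dep, ]
  cd <- great_circle_km(cbind(trip$lon, trip$lat),
                        matrix(c(168.188, -44.188), nrow(trip), 2,
                               byrow = TRUE))
  expect_equal(detect_reversal(trip), trip$date[which.max(cd)])

  # plateau of equal maxima: first day wins
  d2 <- make_daily(out = 8)
  d2 <- dplyr::bind_rows(d2, d2[rep(nrow(d2), 2), ])
  d2$date <- d2$date[1] + seq_len(nrow(d2)) - 1
  d2$mean_time <- as.POSIXct(paste(d2$date, "12:00:00"), tz = "UTC")
  cd2 <- great_circle_km(cbind(d2$lon, d2$lat),
                         matrix(c(168.188, -44.188), nrow(d2), 2,
                                byrow = TRUE))
  expect_equal(detect_reversal(d2), d2$date[which(cd2 == max(cd2))[1]])

  # still receding at the last fix: no reversal
  d3 <- make_daily(out = 15)
  expect_true(is.na(detect_reversal(d3)))
})

test_that("landfall is the first post-reversal day inside the coast buffer", {
  coast <- test_coast()
  d <- make_daily(out = 10, inbound = TRUE)
  dep <- detect_final_departure(d)
  trip <- d[d$date >= dep, ]
  rev <- detect_reversal(trip)
  lf <- detect_landfall(trip, rev, coast)
  cd <- coast_distance_km(cbind(trip$lon, trip$lat), coast)
  expect_equal(lf, trip$date[trip$date > rev & cd < 5][1])

  # track ending 200 km offshore: none
  d2 <- make_daily(out = 10, loiter = 3)
  expect_true(is.na(detect_landfall(d2, detect_reversal(d2), coast)))
  expect_error(detect_landfall(d2, Sys.Date(), NULL), "coastline")

  # coast distance equals the planar point-to-segment oracle at small scale
  ctr <- c(168.188, -44.188)
  seg <- coastline(aeqd_unproject(rbind(c(0, -50), c(0, 50)), ctr))
  pts_xy <- rbind(c(10, 0), c(25, 30), c(3, -60))
  got <- coast_distance_km(aeqd_unproject(pts_xy, ctr), seg)
  planar <- c(10, 25, sqrt(3^2 + 10^2))
  expect_close(got, planar, 0.05)
})

test_that("trip summaries carry the documented conventions", {
  coast <- test_coast()
  d <- make_daily(out = 20, loiter = 5, inbound = TRUE, step_km = 90)
  tr <- summarize_trip(d, coast, sex = "female", body_mass_kg = 3.0)
  expect_equal(tr$status, "complete")
  expect_equal(tr$duration_days,
               as.numeric(tr$end_date - tr$departure_date))
  expect_equal(tr$outward_days,
               as.numeric(tr$reversal_date - tr$departure_date))
  expect_equal(tr$inbound_days,
               as.numeric(tr$landfall_date - tr$reversal_date))
  expect_true(tr$max_range_km <= tr$trip_length_km)

  # max range equals the brute-force maximum over daily positions
  trip_days <- d[d$date >= tr$departure_date & d$date <= tr$end_date, ]
  cd <- great_circle_km(cbind(trip_days$lon, trip_days$lat),
                        matrix(c(168.188, -44.188), nrow(trip_days), 2,
                               byrow = TRUE))
  expect_equal(tr$max_range_km, max(cd), tolerance = 1e-9)

  # outward and inbound phase points partition the at-sea track
  daily_all <- d
  outp <- phase_points(tr, daily_all, "outward")
  inp <- phase_points(tr, daily_all, "inward")
  expect_equal(nrow(outp) + nrow(inp),
               sum(d$date >= tr$departure_date & d$date <= tr$landfall_date))
  expect_equal(length(intersect(outp$date, inp$date)), 0)

  # duration convention reproduces printed whole-day differences
  expect_equal(as.numeric(as.Date("2017-02-22") - as.Date("2016-12-18")), 66)
  expect_equal(as.numeric(as.Date("2017-02-20") - as.Date("2016-12-05")), 77)

  # an out-only track is outward-incomplete with no destination label
  d2 <- make_daily(out = 12)
  tr2 <- summarize_trip(d2, coast)
  expect_equal(tr2$status, "outward_incomplete")
  expect_true(is.na(tr2$destination))
})

test_that("destination labels split at the front boundary latitude", {
  cfgT <- trip_config()
  expect_equal(classify_destination(c(160, -48), cfgT), "STF")
  expect_equal(classify_destination(c(160, -55), cfgT), "SAF")
  # the nine printed birds: a boundary between the two max-range groups
  # reproduces the printed 4 STF / 5 SAF labels
  t1 <- tawaki_table1()
  nine <- t1[!is.na(t1$reversal_date), ]
  lab <- ifelse(nine$max_range_km > 1800, "SAF", "STF")
  expect_equal(lab, nine$destination)
  expect_equal(sum(lab == "STF"), 4)
  expect_equal(sum(lab == "SAF"), 5)
})

test_that("relative trip time maps departure to 0 and landfall to 1", {
  tr <- tibble::tibble(departure_date = as.Date("2016-12-18"),
                       landfall_date = as.Date("2017-02-22"))
  expect_equal(relative_trip_time(tr$departure_date, tr), 0)
  expect_equal(relative_trip_time(tr$landfall_date, tr), 1)
  expect_equal(relative_trip_time(tr$departure_date + 33, tr), 0.5)
  tr$landfall_date <- as.Date(NA)
  expect_error(relative_trip_time(tr$departure_date, tr), "complete")
})

test_that("cohort summaries use sort-based medians over defined subsets", {
  trips <- table1_as_trips()
  cs <- cohort_summary(trips)
  mr <- cs[cs$statistic == "max_range_km", ]
  expect_equal(mr$n, 9)
  expect_equal(mr$median, 1973)
  tl <- cs[cs$statistic == "trip_length_km", ]
  expect_equal(tl$n, 5)
  expect_equal(tl$median, 5381)
  rv <- cs[cs$statistic == "reversal_date", ]
  expect_equal(rv$median_date, as.Date("2017-01-06"))

  # single-trip subsets collapse to the value itself
  cs1 <- cohort_summary(trips[1, ])
  tl1 <- cs1[cs1$statistic == "trip_length_km", ]
  expect_true(tl1$median == tl1$min && tl1$min == tl1$max)

  # sort-based oracle on random inputs (even n: mean of central pair)
  set.seed(3)
  for (i in 1:20) {
    x <- rnorm(sample(2:15, 1))
    s <- sort(x); n <- length(s)
    manual <- if (n %% 2) s[(n + 1) / 2] else mean(s[n / 2 + 0:1])
    expect_equal(stats::median(x), manual)
  }

  # empty subsets are undefined, not zero
  cs2 <- cohort_summary(trips[trips$status == "outward_incomplete", ])
  expect_true(is.na(cs2$median[cs2$statistic == "trip_length_km"]))
})
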
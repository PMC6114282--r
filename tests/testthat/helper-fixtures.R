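# Shared fixture builders. Everything is generated in code; expensive
# cohorts are memoised so several test files can reuse one simulation.

.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(key, config) {
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- simulate_cohort(config)
  .cohort_cache[[key]]
}

# A clean daily track: departure after `pre` colony days, `out` outbound
# days at `step_km`/day heading south-west, `loiter` small-step days,
# then inbound back to the colony.
make_daily <- function(bird_id = "T1", colony = c(168.188, -44.188),
                       start = as.Date("2016-12-01"), pre = 0, out = 20,
                       loiter = 0, inbound = FALSE, step_km = 80) {
  xy <- matrix(c(0.5, 0), 1, 2)
  for (i in seq_len(max(0, pre - 1))) xy <- rbind(xy, c(0.5, 0))
  dirv <- c(sin(230 * pi / 180), cos(230 * pi / 180))
  pos <- xy[nrow(xy), ]
  for (i in seq_len(out)) { pos <- pos + step_km * dirv; xy <- rbind(xy, pos) }
  for (i in seq_len(loiter)) {
    pos <- pos + 5 * c(sin(i), cos(i)); xy <- rbind(xy, pos)
  }
  if (inbound) {
    while (sqrt(sum(pos^2)) > step_km) {
      pos <- pos - step_km * pos / sqrt(sum(pos^2)); xy <- rbind(xy, pos)
    }
    xy <- rbind(xy, c(0.5, 0))
  }
  ll <- aeqd_unproject(xy, colony)
  n <- nrow(xy)
  dates <- start + seq_len(n) - 1
  tibble::tibble(bird_id = bird_id, date = dates,
                 mean_time = as.POSIXct(paste(dates, "12:00:00"), tz = "UTC"),
                 lon = ll[, 1], lat = ll[, 2], n_fixes = 1L)
}

# Straight synthetic coast through the colony (same shape the simulator
# uses), for landfall tests.
test_coast <- function(colony = c(168.188, -44.188)) {
  yy <- seq(-300, 300, by = 20)
  coastline(aeqd_unproject(cbind(0.06 * yy, yy), colony))
}

expect_close <- function(x, y, tol) expect_true(all(abs(x - y) <= tol))
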
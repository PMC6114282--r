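#' Mean time of day as an instant
#'
#' Arithmetic mean of the epoch (UNIX) seconds of a set of timestamps,
#' all on one UTC calendar day, back-converted to POSIXct.
#'
#' @param timestamps POSIXct vector, all on one UTC date.
#' @return POSIXct (UTC) mean instant.
#' @export
mean_epoch_time <- function(timestamps) {
  stopifnot(length(timestamps) >= 1)
  dates <- unique(as.Date(timestamps, tz = "UTC"))
  if (length(dates) > 1) stop("timestamps span multiple UTC dates")
  as.POSIXct(mean(as.numeric(timestamps)), origin = "1970-01-01", tz = "UTC")
}

#' Geographic mean of points on the sphere
#'
#' Points are mapped to unit 3-vectors, averaged and renormalised, then
#' mapped back to lon/lat; this is antimeridian-safe. A symmetric
#' antipodal set has zero resultant and raises an error instead of
#' returning an arbitrary point.
#'
#' @param lonlat Two-column matrix (lon, lat) in degrees.
#' @return `c(lon, lat)` of the spherical mean.
#' @export
geographic_mean <- function(lonlat) {
  lonlat <- rbind(lonlat)
  stopifnot(nrow(lonlat) >= 1)
  check_lonlat(lonlat)
  rad <- pi / 180
  x <- mean(cos(lonlat[, 2] * rad) * cos(lonlat[, 1] * rad))
  y <- mean(cos(lonlat[, 2] * rad) * sin(lonlat[, 1] * rad))
  z <- mean(sin(lonlat[, 2] * rad))
  r <- sqrt(x^2 + y^2 + z^2)
  if (r < 1e-12) stop("degenerate point set: zero resultant vector")
  c(lon = atan2(y, x) / rad, lat = asin(z / r) / rad)
}

#' Collapse filtered fixes to one position per bird and UTC day
#'
#' For each (bird, UTC date) group, the representative time is the mean
#' of the fixes' epoch seconds and the representative position the
#' geographic mean of their coordinates, leaving a single mean time and
#' position per day and individual.
#'
#' @param fixes Tibble of filtered fixes (`bird_id`, `time`, `lon`,
#'   `lat`), or a `filter_result` whose `retained` element is used.
#' @return Tibble of daily positions: `bird_id`, `date`, `mean_time`,
#'   `lon`, `lat`, `n_fixes`, chronological within bird.
#' @export
daily_aggregate <- function(fixes) {
  if (inherits(fixes, "filter_result")) fixes <- fixes$retained
  stopifnot(nrow(fixes) >= 1)
  fixes <- fixes[order(fixes$bird_id, fixes$time), ]
  fixes$date <- as.Date(fixes$time, tz = "UTC")
  out <- lapply(split(fixes, list(fixes$bird_id, fixes$date), drop = TRUE),
    function(g) {
      gm <- geographic_mean(cbind(g$lon, g$lat))
      tibble::tibble(bird_id = g$bird_id[1], date = g$date[1],
                     mean_time = mean_epoch_time(g$time),
                     lon = unname(gm[1]), lat = unname(gm[2]),
                     n_fixes = nrow(g))
    })
  out <- dplyr::bind_rows(out)
  out[order(out$bird_id, out$date), ]
}

#' Daily travel distances and speeds
#'
#' Great-circle distances between consecutive mean daily positions of
#' one bird, with elapsed time from the mean-time difference. `km_day`
#' normalises the step distance by the elapsed calendar days, so a
#' km-per-day rate is well defined across days without fixes.
#'
#' @param daily Daily positions of a single bird ([daily_aggregate()]).
#' @param geodesy A [geodesy_config()].
#' @return Tibble of steps: `bird_id`, `from_date`, `to_date`,
#'   `distance_km`, `elapsed_h`, `speed_kmh`, `km_day`.
#' @export
daily_steps <- function(daily, geodesy = geodesy_config()) {
  stopifnot(nrow(daily) >= 2, length(unique(daily$bird_id)) == 1)
  daily <- daily[order(daily$date), ]
  if (any(diff(as.numeric(daily$mean_time)) <= 0))
    stop("mean_time must strictly increase")
  n <- nrow(daily)
  a <- cbind(daily$lon[-n], daily$lat[-n])
  b <- cbind(daily$lon[-1], daily$lat[-1])
  d <- great_circle_km(a, b, geodesy)
  eh <- diff(as.numeric(daily$mean_time)) / 3600
  tibble::tibble(bird_id = daily$bird_id[1],
                 from_date = daily$date[-n], to_date = daily$date[-1],
                 distance_km = d, elapsed_h = eh, speed_kmh = d / eh,
                 km_day = d / as.numeric(diff(daily$date)))
}
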
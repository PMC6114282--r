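#' Trip segmentation configuration
#'
#' @param colony `c(lon, lat)` of the deployment site.
#' @param coast_buffer_km Distance to coast below which a bird is "in
#'   mainland waters" (landfall), km.
#' @param departure_dist_km Colony distance above which a day counts as
#'   "away", km.
#' @param front_boundary_lat Latitude (degrees, negative south)
#'   separating Subtropical Front (north) from Subantarctic Front
#'   (south) destination labels.
#' @param min_away_days Minimum span of an away-run to count as the
#'   final departure rather than a pre-departure foraging sortie.
#' @return A list of class `trip_config`.
#' @export
trip_config <- function(colony = c(168.188, -44.188), coast_buffer_km = 5,
                        departure_dist_km = 20, front_boundary_lat = -52,
                        min_away_days = 3) {
  stopifnot(coast_buffer_km > 0, departure_dist_km > 0, min_away_days > 0,
            front_boundary_lat > -90, front_boundary_lat < 0)
  structure(list(colony = colony, coast_buffer_km = coast_buffer_km,
                 departure_dist_km = departure_dist_km,
                 front_boundary_lat = front_boundary_lat,
                 min_away_days = min_away_days),
            class = "trip_config")
}

colony_distance_km <- function(daily, config, geodesy = geodesy_config()) {
  great_circle_km(cbind(daily$lon, daily$lat),
                  matrix(config$colony, nrow(daily), 2, byrow = TRUE),
                  geodesy)
}

# Maximal runs of TRUE in a logical vector: tibble of start/end indices.
logical_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble::tibble(start = starts[r$values], end = ends[r$values])
}

#' Detect the final departure day
#'
#' Penguins make short coastal foraging sorties before leaving for good;
#' these must be excluded from trip statistics. The final departure is
#' the first day of the last maximal run of days with colony distance
#' greater than `departure_dist_km` that spans at least `min_away_days`
#' days.
#'
#' @param daily One bird's daily positions.
#' @param config A [trip_config()].
#' @param geodesy A [geodesy_config()].
#' @return The departure `Date`.
#' @export
detect_final_departure <- function(daily, config = trip_config(),
                                   geodesy = geodesy_config()) {
  daily <- daily[order(daily$date), ]
  d <- colony_distance_km(daily, config, geodesy)
  runs <- logical_runs(d > config$departure_dist_km)
  if (nrow(runs)) {
    span <- as.numeric(daily$date[runs$end] - daily$date[runs$start]) + 1
    runs <- runs[span >= config$min_away_days, ]
  }
  if (!nrow(runs)) stop("no departure detected")
  daily$date[runs$start[nrow(runs)]]
}

#' Detect the trip reversal day
#'
#' The day a bird stops moving away and begins homeward travel,
#' operationalised as the day of maximum great-circle distance from the
#' deployment site (ties to the earliest such day). If the track is
#' still receding at its last fix -- the maximum falls on the final day
#' and the last three days' distances are still increasing on average --
#' no reversal is returned.
#'
#' @param daily One bird's daily positions, already restricted to dates
#'   on/after departure.
#' @param config A [trip_config()].
#' @param geodesy A [geodesy_config()].
#' @return The reversal `Date`, or `NA` if the track is still receding.
#' @export
detect_reversal <- function(daily, config = trip_config(),
                            geodesy = geodesy_config()) {
  daily <- daily[order(daily$date), ]
  d <- colony_distance_km(daily, config, geodesy)
  i <- which.max(d)                      # earliest day on ties
  n <- length(d)
  if (i == n && n >= 2) {
    tail_d <- utils::tail(d, 3)
    if (mean(diff(tail_d)) > 0) return(as.Date(NA))
  }
  daily$date[i]
}

#' Detect the landfall day
#'
#' First day on or after the reversal whose position lies within
#' `coast_buffer_km` of the coastline.
#'
#' @param daily One bird's daily positions from departure onward.
#' @param reversal_date Reversal date from [detect_reversal()].
#' @param coast A [coastline()].
#' @param config A [trip_config()].
#' @param geodesy A [geodesy_config()].
#' @return The landfall `Date`, or `NA` if the bird never re-entered
#'   mainland waters before the track ended.
#' @export
detect_landfall <- function(daily, reversal_date, coast,
                            config = trip_config(),
                            geodesy = geodesy_config()) {
  if (is.null(coast)) stop("coastline required for landfall detection")
  if (is.na(reversal_date)) return(as.Date(NA))
  post <- daily[daily$date > reversal_date, , drop = FALSE]
  if (!nrow(post)) return(as.Date(NA))
  cd <- coast_distance_km(cbind(post$lon, post$lat), coast, geodesy)
  hit <- which(cd < config$coast_buffer_km)
  if (!length(hit)) return(as.Date(NA))
  post$date[hit[1]]
}

#' Classify the trip destination
#'
#' Trip destinations fall into two broad regions: south of the
#' Subtropical Front (STF) and near the Subantarctic Front (SAF). The
#' label is assigned from the latitude of the maximum-range position
#' against a configurable boundary latitude.
#'
#' @param max_range_position `c(lon, lat)` of the furthest position.
#' @param config A [trip_config()].
#' @return `"SAF"` or `"STF"`.
#' @export
classify_destination <- function(max_range_position, config = trip_config()) {
  if (max_range_position[2] < config$front_boundary_lat) "SAF" else "STF"
}

#' Summarise one bird's pre-moult trip
#'
#' Segments a daily track into pre-departure, outward, and inbound
#' phases and computes the per-bird trip statistics: duration (whole-day
#' difference between trip end and departure), trip length (cumulative
#' sum of daily step distances), maximum range (greatest great-circle
#' distance from the deployment site), destination label, completeness
#' status, and the median and range of the daily travel distance
#' (km/day, step distance normalised by elapsed days).
#'
#' Outward days are `reversal - departure` and inbound days
#' `landfall - reversal`; birds may loiter near the apex, so these
#' conventions are stated rather than inferred.
#'
#' @param daily One bird's daily positions.
#' @param coast A [coastline()] or `NULL` (landfall then undetectable).
#' @param config A [trip_config()].
#' @param sex,body_mass_kg Optional bird metadata.
#' @param geodesy A [geodesy_config()].
#' @return One-row tibble (`trip_summary`).
#' @export
summarize_trip <- function(daily, coast = NULL, config = trip_config(),
                           sex = NA_character_, body_mass_kg = NA_real_,
                           geodesy = geodesy_config()) {
  stopifnot(length(unique(daily$bird_id)) == 1)
  daily <- daily[order(daily$date), ]
  departure <- detect_final_departure(daily, config, geodesy)
  trip <- daily[daily$date >= departure, , drop = FALSE]
  reversal <- detect_reversal(trip, config, geodesy)
  landfall <- if (!is.null(coast))
    detect_landfall(trip, reversal, coast, config, geodesy) else as.Date(NA)

  end_date <- if (!is.na(landfall)) landfall else max(trip$date)
  trip <- trip[trip$date <= end_date, , drop = FALSE]

  d_colony <- colony_distance_km(trip, config, geodesy)
  i_max <- which.max(d_colony)
  steps <- if (nrow(trip) >= 2) daily_steps(trip, geodesy) else NULL
  trip_len <- if (is.null(steps)) 0 else sum(steps$distance_km)
  kmd <- if (is.null(steps)) numeric(0) else steps$km_day

  status <- if (!is.na(landfall)) "complete"
            else if (!is.na(reversal)) "inbound_incomplete"
            else "outward_incomplete"
  dest <- if (!is.na(reversal))
    classify_destination(c(trip$lon[i_max], trip$lat[i_max]), config)
    else NA_character_

  tibble::tibble(
    bird_id = daily$bird_id[1], sex = sex, body_mass_kg = body_mass_kg,
    departure_date = departure, reversal_date = reversal,
    landfall_date = landfall, end_date = end_date,
    duration_days = as.numeric(end_date - departure),
    outward_days = as.numeric(reversal - departure),
    inbound_days = as.numeric(landfall - reversal),
    trip_length_km = trip_len, max_range_km = max(d_colony),
    max_range_lon = trip$lon[i_max], max_range_lat = trip$lat[i_max],
    destination = dest, status = status,
    daily_km_median = if (length(kmd)) stats::median(kmd) else NA_real_,
    daily_km_min = if (length(kmd)) min(kmd) else NA_real_,
    daily_km_max = if (length(kmd)) max(kmd) else NA_real_)
}

#' Relative trip time
#'
#' Maps the days of a complete trip onto \[0, 1\]: 0 at departure, 1 at
#' landfall, so trips of different absolute length are comparable.
#'
#' @param dates Vector of dates.
#' @param trip One-row trip summary of a complete trip.
#' @return Numeric vector in \[0, 1\].
#' @export
relative_trip_time <- function(dates, trip) {
  if (is.na(trip$landfall_date)) stop("relative trip time needs a complete trip")
  as.numeric(dates - trip$departure_date) /
    as.numeric(trip$landfall_date - trip$departure_date)
}

# Median with even-n mean-of-central-pair, on day offsets for dates.
stat_row <- function(name, subset_name, x) {
  if (is.null(x) || !length(x) || all(is.na(x))) {
    return(tibble::tibble(statistic = name, subset = subset_name, n = 0L,
                          median = NA, min = NA, max = NA))
  }
  x <- x[!is.na(x)]
  is_date <- inherits(x, "Date")
  v <- as.numeric(x)
  med <- stats::median(v)
  out <- tibble::tibble(statistic = name, subset = subset_name,
                        n = length(v), median = med, min = min(v),
                        max = max(v))
  if (is_date) {
    out$median_date <- as.Date(med, origin = "1970-01-01")
    out$min_date <- as.Date(min(v), origin = "1970-01-01")
    out$max_date <- as.Date(max(v), origin = "1970-01-01")
  }
  out
}

#' Cohort-level trip statistics
#'
#' Medians and ranges of the main trip parameters over the subsets on
#' which each is defined: departure over all birds, reversal date,
#' outward days and maximum range over birds with a reversal, and
#' inbound days, duration and trip length over complete trips. Date
#' medians are computed on day offsets and back-converted; an empty
#' subset yields an undefined (NA) statistic, never zero.
#'
#' @param trips Trip-summary tibble (one row per bird).
#' @return Tibble with columns `statistic`, `subset`, `n`, `median`,
#'   `min`, `max` (plus `*_date` columns for date statistics).
#' @export
cohort_summary <- function(trips) {
  stopifnot(nrow(trips) >= 1)
  rev_birds <- trips[!is.na(trips$reversal_date), ]
  complete <- trips[trips$status == "complete", ]
  dplyr::bind_rows(
    stat_row("departure_date", "all", trips$departure_date),
    stat_row("reversal_date", "with_reversal", rev_birds$reversal_date),
    stat_row("outward_days", "with_reversal", rev_birds$outward_days),
    stat_row("max_range_km", "with_reversal", rev_birds$max_range_km),
    stat_row("inbound_days", "complete", complete$inbound_days),
    stat_row("duration_days", "complete", complete$duration_days),
    stat_row("trip_length_km", "complete", complete$trip_length_km),
    stat_row("daily_km_median", "with_reversal", rev_birds$daily_km_median))
}
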
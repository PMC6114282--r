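#' Published per-bird trip statistics
#'
#' Transcription of the published table of individual trip statistics
#' for the 17 satellite-tracked birds (five complete trips, four with an
#' incomplete inbound journey, eight with an incomplete outward
#' journey), shipped with the package for regression tests and for
#' fitting the trip-parameter models when raw tracks are unavailable.
#'
#' @return Tibble with one row per bird: identity, sex, body mass,
#'   trip start/end dates, duration, landfall location, trip length and
#'   maximum range (km), destination label, reversal date, outward and
#'   inbound day counts, and the median/min/max daily travel distance.
#' @export
tawaki_table1 <- function() {
  p <- system.file("extdata", "table1.csv", package = "tawakitrack",
                   mustWork = TRUE)
  d <- utils::read.csv(p, stringsAsFactors = FALSE)
  d$trip_start <- as.Date(d$trip_start)
  d$trip_end <- as.Date(d$trip_end)
  d$reversal_date <- as.Date(d$reversal_date)
  d$destination[d$destination == ""] <- NA
  d$landfall_loc[d$landfall_loc == ""] <- NA
  tibble::as_tibble(d)
}

#' Published mixed-model estimates for the main trip parameters
#'
#' Transcription of the published fixed-effect tables (destination + sex
#' models with a per-bird random intercept; reference levels SAF
#' destination and female sex). Used by the pipeline regression report.
#'
#' @return Tibble with columns `param`, `term`, `estimate`,
#'   `estimate_date`, `se`, `df`, `t`, `p`.
#' @export
tawaki_table2 <- function() {
  p <- system.file("extdata", "table2.csv", package = "tawakitrack",
                   mustWork = TRUE)
  d <- utils::read.csv(p, stringsAsFactors = FALSE,
                       colClasses = c(p = "character"))
  d$estimate_date <- as.Date(ifelse(d$estimate_date == "", NA,
                                    d$estimate_date))
  tibble::as_tibble(d)
}

#' Map the published per-bird table onto the trip-summary layout
#'
#' Renames/derives columns so the packaged table can be fed directly to
#' [fit_trip_lmm()] and [cohort_summary()] ("fixture mode": the raw
#' Argos tracks behind the publication were not deposited).
#'
#' @return Trip-summary tibble (one row per bird).
#' @export
table1_as_trips <- function() {
  t1 <- tawaki_table1()
  tibble::tibble(
    bird_id = t1$bird_id, sex = t1$sex, body_mass_kg = t1$body_mass_kg,
    departure_date = t1$trip_start, reversal_date = t1$reversal_date,
    landfall_date = as.Date(ifelse(t1$status == "complete",
                                   as.character(t1$trip_end), NA)),
    end_date = t1$trip_end, duration_days = t1$duration_days,
    outward_days = t1$outward_days, inbound_days = t1$inbound_days,
    trip_length_km = t1$trip_length_km, max_range_km = t1$max_range_km,
    max_range_lon = NA_real_, max_range_lat = NA_real_,
    destination = t1$destination, status = t1$status,
    daily_km_median = t1$daily_km_median,
    daily_km_min = t1$daily_km_min, daily_km_max = t1$daily_km_max)
}
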
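#' Simulation configuration for an Argos-like cohort
#'
#' Defaults emulate the study conditions of the tracked cohort: 17
#' birds, 1-8 uplinks per day, roughly half the fixes in the
#' no-accuracy-estimate classes A/B, pre-departure coastal sorties, a
#' south-west outbound corridor, destination ranges of order 1,500 and
#' 2,200 km, and a loiter (destination) phase of 10-20 days before the
#' inbound leg.
#'
#' @param n_birds Number of birds.
#' @param colony `c(lon, lat)` of the deployment site.
#' @param start_date First tracking day.
#' @param outbound_heading Mean outbound bearing, degrees (230 = SW).
#' @param heading_sd Daily heading sd about the corridor, degrees.
#' @param mean_daily_km_range Range from which each bird's mean daily
#'   travel (km/day) is drawn.
#' @param loiter_days_range Range of days spent at the destination.
#' @param destination_range_km The two destination-regime ranges (km).
#' @param fixes_per_day Integer range of uplinks per day.
#' @param class_mix Named probabilities over location classes
#'   3/2/1/0/A/B (sums to 1; default puts 49% in A+B).
#' @param class_error_sd_m Named per-axis error sd (m) per class.
#' @param heavy_tail_prob Probability a fix's error is drawn at
#'   `heavy_tail_scale` times its class sd (heavy-tailed Argos errors).
#' @param heavy_tail_scale Scale multiplier for heavy-tail errors.
#' @param outlier_rate Fraction of fixes replaced by 50-500 km
#'   displacements.
#' @param pre_departure_trips Number of short coastal foraging sorties
#'   before final departure.
#' @param status_probs Probabilities of `complete`,
#'   `inbound_incomplete`, `outward_incomplete` censoring (default the
#'   observed 5/4/8 of 17).
#' @param seed Integer master seed; one RNG stream is derived per bird
#'   from (seed, bird index).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_birds = 17, colony = c(168.188, -44.188),
                       start_date = as.Date("2016-11-15"),
                       outbound_heading = 230, heading_sd = 12,
                       mean_daily_km_range = c(40, 80),
                       loiter_days_range = c(10, 20),
                       destination_range_km = c(1500, 2200),
                       fixes_per_day = c(1, 8),
                       class_mix = c("3" = 0.08, "2" = 0.12, "1" = 0.15,
                                     "0" = 0.16, "A" = 0.24, "B" = 0.25),
                       class_error_sd_m = c("3" = 150, "2" = 400,
                                            "1" = 1200, "0" = 3000,
                                            "A" = 5000, "B" = 10000),
                       heavy_tail_prob = 0.05, heavy_tail_scale = 5,
                       outlier_rate = 0, pre_departure_trips = 2,
                       status_probs = c(complete = 5 / 17,
                                        inbound_incomplete = 4 / 17,
                                        outward_incomplete = 8 / 17),
                       seed = 1) {
  stopifnot(abs(sum(class_mix) - 1) < 1e-9, all(class_error_sd_m > 0),
            all(mean_daily_km_range > 0), all(destination_range_km > 0),
            outlier_rate >= 0, outlier_rate <= 1,
            abs(sum(status_probs) - 1) < 1e-9)
  structure(as.list(environment()), class = "sim_config")
}

bird_seed <- function(seed, bird_index) {
  (as.integer(seed) %% 100000L) * 20011L + 7L * as.integer(bird_index)
}

# sample() treats a length-1 x as 1:x; this does not.
sample_int <- function(from, to) {
  if (from == to) return(from)
  sample(from:to, 1)
}

# The synthetic mainland coast: a gently angled north-south polyline
# through the colony (the colony sits on the coast).
#' Synthetic coastline used by the simulator
#'
#' @param config A [sim_config()].
#' @param geodesy A [geodesy_config()].
#' @return A [coastline()] running ~600 km north-south through the
#'   colony.
#' @export
synthetic_coastline <- function(config = sim_config(),
                                geodesy = geodesy_config()) {
  yy <- seq(-300, 300, by = 20)
  xx <- 0.06 * yy   # slightly angled, like the south Westland coast
  coastline(aeqd_unproject(cbind(xx, yy), config$colony, geodesy))
}

wrap_heading <- function(h) ((h + 180) %% 360) - 180

#' Simulate one bird's pre-moult track
#'
#' Builds a three-phase correlated random walk in the
#' azimuthal-equidistant plane about the colony -- outbound within a
#' corridor around the configured heading, a small-step loiter phase at
#' the destination, and an inbound leg back to the colony -- preceded by
#' short pre-departure coastal sorties. Daily true positions are then
#' observed as 1-8 Argos fixes per day with class-dependent isotropic
#' noise (heavy-tailed mixture) and an optional fraction of 50-500 km
#' outliers. Censoring per `status`: `outward_incomplete` tracks are
#' truncated mid-outbound, `inbound_incomplete` between reversal and
#' landfall.
#'
#' @param config A [sim_config()].
#' @param bird_index Index of the bird (sets its RNG stream).
#' @param status Censoring status.
#' @param regime Destination regime, 1 (near) or 2 (far); default
#'   alternates by bird.
#' @param geodesy A [geodesy_config()].
#' @return List with `fixes` (Argos-like tibble with an `outlier`
#'   column) and `truth` (true daily path, true
#'   departure/reversal/landfall dates, loiter window, regime).
#' @export
simulate_track <- function(config = sim_config(), bird_index = 1,
                           status = "complete", regime = NULL,
                           geodesy = geodesy_config()) {
  status <- match.arg(status, names(config$status_probs))
  set.seed(bird_seed(config$seed, bird_index))
  if (is.null(regime)) regime <- 1 + bird_index %% 2
  dest_km <- config$destination_range_km[regime]
  vbar <- stats::runif(1, config$mean_daily_km_range[1],
                       config$mean_daily_km_range[2])
  loiter_days <- sample_int(config$loiter_days_range[1],
                            config$loiter_days_range[2])

  # --- true daily path in the projected plane (km), colony at origin.
  # Pre-departure: the bird rests ashore at the colony, interrupted by
  # one-day out-and-back foraging sorties (tracked per day in day_type).
  colony_xy <- c(0.5, 0)  # nest site, just off the coast vertex
  xy <- matrix(colony_xy, 2, 2, byrow = TRUE)
  day_type <- c("colony", "colony")
  sortie <- list(NULL, NULL)
  for (s in seq_len(config$pre_departure_trips)) {
    xy <- rbind(xy, colony_xy, colony_xy)
    day_type <- c(day_type, "sortie", "colony")
    sortie <- c(sortie,
                list(list(r = stats::runif(1, 25, 40),
                          ang = stats::runif(1, 180, 300) * pi / 180)),
                list(NULL))
  }
  n_pre <- nrow(xy)

  heading <- config$outbound_heading + stats::rnorm(1, 0, 5)
  pos <- colony_xy
  max_outbound_days <- ceiling(4 * dest_km / max(5, vbar))
  repeat {  # outbound
    heading <- config$outbound_heading +
      0.6 * (heading - config$outbound_heading) +
      stats::rnorm(1, 0, config$heading_sd)
    step <- max(5, stats::rnorm(1, vbar, 0.12 * vbar))
    pos <- pos + step * c(sin(heading * pi / 180), cos(heading * pi / 180))
    xy <- rbind(xy, pos)
    if (sqrt(sum(pos^2)) >= dest_km) break
    if (nrow(xy) - n_pre > max_outbound_days)
      stop("outbound phase failed to reach the destination range")
  }
  reversal_start <- nrow(xy)
  for (d in seq_len(loiter_days)) {  # loiter: small-step movement
    pos <- pos + stats::runif(1, 3, 18) *
      c(sin(stats::runif(1, 0, 2 * pi)), cos(stats::runif(1, 0, 2 * pi)))
    xy <- rbind(xy, pos)
  }
  loiter_end <- nrow(xy)
  repeat {  # inbound: home toward the colony
    to_home <- -pos
    dist_home <- sqrt(sum(to_home^2))
    step <- max(5, stats::rnorm(1, vbar, 0.12 * vbar))
    if (dist_home <= step) { xy <- rbind(xy, c(0.5, 0)); break }
    bear <- atan2(to_home[1], to_home[2]) + stats::rnorm(1, 0, 0.12)
    pos <- pos + step * c(sin(bear), cos(bear))
    xy <- rbind(xy, pos)
  }
  landfall_day <- nrow(xy)
  xy <- rbind(xy, c(0.5, 0), c(0.5, 0))  # post-landfall colony days

  dist_colony <- sqrt(rowSums(xy^2))
  true_reversal_day <- which.max(dist_colony)

  # censoring
  last_day <- nrow(xy)
  if (status == "outward_incomplete") {
    cut <- n_pre + max(3, floor(stats::runif(1, 0.25, 0.85) *
                                (reversal_start - n_pre)))
    last_day <- min(cut, reversal_start - 1)
  } else if (status == "inbound_incomplete") {
    last_day <- loiter_end +
      max(2, floor(stats::runif(1, 0.3, 0.8) * (landfall_day - loiter_end)))
    last_day <- min(last_day, landfall_day - 2)
  }
  xy <- xy[seq_len(last_day), , drop = FALSE]
  dist_colony <- dist_colony[seq_len(last_day)]

  dates <- config$start_date + seq_len(nrow(xy)) - 1
  lonlat <- aeqd_unproject(xy, config$colony, geodesy)
  truth_path <- tibble::tibble(
    bird_id = sprintf("S%02d", bird_index), date = dates,
    x_km = xy[, 1], y_km = xy[, 2],
    lon = lonlat[, 1], lat = lonlat[, 2], dist_colony_km = dist_colony)

  # --- observe as Argos fixes
  classes <- names(config$class_mix)
  rows <- list()
  for (i in seq_len(nrow(xy))) {
    nf <- sample_int(config$fixes_per_day[1], config$fixes_per_day[2])
    secs <- sort(stats::runif(nf, 0, 86399))
    frac <- secs / 86400
    dtp <- if (i <= length(day_type)) day_type[i] else "transit"
    if (dtp == "sortie") {        # out-and-back within the day
      si <- sortie[[i]]
      rr <- si$r * sin(pi * frac)
      px <- colony_xy[1] + rr * sin(si$ang)
      py <- colony_xy[2] + rr * cos(si$ang)
    } else if (dtp == "colony") { # ashore/nearshore at the nest
      px <- rep(xy[i, 1], nf)
      py <- rep(xy[i, 2], nf)
    } else {                      # at-sea transit: within-day interpolation
      nxt <- if (i < nrow(xy)) xy[i + 1, ] else xy[i, ]
      px <- xy[i, 1] + frac * (nxt[1] - xy[i, 1])
      py <- xy[i, 2] + frac * (nxt[2] - xy[i, 2])
    }
    lc <- sample(classes, nf, replace = TRUE, prob = config$class_mix)
    sdk <- config$class_error_sd_m[lc] / 1000
    heavy <- stats::runif(nf) < config$heavy_tail_prob
    sdk[heavy] <- sdk[heavy] * config$heavy_tail_scale
    ex <- stats::rnorm(nf, 0, sdk); ey <- stats::rnorm(nf, 0, sdk)
    is_out <- stats::runif(nf) < config$outlier_rate
    if (any(is_out)) {
      r <- stats::runif(sum(is_out), 50, 500)
      a <- stats::runif(sum(is_out), 0, 2 * pi)
      ex[is_out] <- r * sin(a); ey[is_out] <- r * cos(a)
    }
    rows[[i]] <- tibble::tibble(
      date = dates[i], secs = secs, x = px + ex, y = py + ey,
      lc = lc, outlier = is_out)
  }
  obs <- dplyr::bind_rows(rows)
  ll <- aeqd_unproject(cbind(obs$x, obs$y), config$colony, geodesy)
  fixes <- tibble::tibble(
    bird_id = sprintf("S%02d", bird_index),
    time = as.POSIXct(as.numeric(as.POSIXct(obs$date, tz = "UTC")) +
                      obs$secs, origin = "1970-01-01", tz = "UTC"),
    lon = ll[, 1], lat = ll[, 2], lc = obs$lc, outlier = obs$outlier)

  truth <- list(
    bird_id = sprintf("S%02d", bird_index), path = truth_path,
    regime = regime, status = status, mean_daily_km = vbar,
    departure_date = dates[n_pre + 1],
    loiter_start = if (last_day >= reversal_start)
      dates[reversal_start] else as.Date(NA),
    loiter_end = if (last_day >= reversal_start)
      dates[min(loiter_end, last_day)] else as.Date(NA),
    reversal_date = if (last_day >= reversal_start)
      dates[min(true_reversal_day, last_day)] else as.Date(NA),
    landfall_date = if (status == "complete")
      dates[landfall_day] else as.Date(NA))
  list(fixes = fixes, truth = truth)
}

#' Simulate a cohort of birds
#'
#' Assigns each bird a destination regime (alternating near/far) and a
#' censoring status drawn to match the configured proportions exactly
#' (largest-remainder rounding), then simulates each track on its own
#' RNG stream.
#'
#' @param config A [sim_config()].
#' @param geodesy A [geodesy_config()].
#' @return List with `fixes` (all birds), `truth` (list per bird),
#'   `statuses`, and the `config`.
#' @export
simulate_cohort <- function(config = sim_config(),
                            geodesy = geodesy_config()) {
  n <- config$n_birds
  if (n == 0)
    return(list(fixes = tibble::tibble(bird_id = character(0)),
                truth = list(), statuses = character(0), config = config))
  counts <- floor(config$status_probs * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- config$status_probs * n - counts
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[add] <- counts[add] + 1
  }
  statuses <- rep(names(counts), counts)
  sims <- lapply(seq_len(n), function(i)
    simulate_track(config, i, status = statuses[i], geodesy = geodesy))
  list(fixes = dplyr::bind_rows(lapply(sims, `[[`, "fixes")),
       truth = lapply(sims, `[[`, "truth"),
       statuses = statuses, config = config)
}
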
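#' Speed-distance-angle filter configuration
#'
#' Parameters of the SDA filter used to clean Argos fixes. `vmax` is the
#' maximum plausible sustained travel speed of the animal; 2.0 m/s is
#' the mean of reported penguin swimming speeds. The spike stage removes
#' out-and-back transmission artefacts: a non-endpoint fix is a spike
#' when its internal turning angle is below `spike_angles[k]` while both
#' adjacent retained step lengths exceed `spike_dists[k]`, for any k.
#'
#' @param vmax Maximum speed in m/s (> 0).
#' @param spike_angles Increasing angle thresholds in degrees.
#' @param spike_dists Increasing distance thresholds in meters, same
#'   length as `spike_angles`.
#' @param drop_class_z Remove invalid (class Z) fixes first?
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(vmax = 2.0, spike_angles = c(15, 25),
                          spike_dists = c(2500, 5000), drop_class_z = TRUE) {
  stopifnot(vmax > 0, length(spike_angles) == length(spike_dists),
            !is.unsorted(spike_angles, strictly = TRUE),
            !is.unsorted(spike_dists, strictly = TRUE))
  structure(list(vmax = vmax, spike_angles = spike_angles,
                 spike_dists = spike_dists, drop_class_z = drop_class_z),
            class = "filter_config")
}

#' Internal turning angle at a fix
#'
#' Angle at `cur` between the great-circle bearings `cur -> prev` and
#' `cur -> next`, in degrees within \[0, 180\]. 180 means straight
#' continuation, 0 a full out-and-back reversal. Coincident points give
#' 180 (no spike) by convention.
#'
#' @param prev,cur,nxt `c(lon, lat)` points.
#' @param geodesy A [geodesy_config()].
#' @return Angle in degrees.
#' @export
turning_angle <- function(prev, cur, nxt, geodesy = geodesy_config()) {
  if (all(prev == cur) || all(nxt == cur)) return(180)
  rad <- pi / 180
  lam <- c(cur[1], prev[1], nxt[1]) * rad
  phi <- c(cur[2], prev[2], nxt[2]) * rad
  b1 <- fast_bearing(lam, phi, 1, 2)
  b2 <- fast_bearing(lam, phi, 1, 3)
  a <- unname((abs(b1 - b2) / rad) %% 360)
  if (a > 180) a <- 360 - a
  a
}

# Vectorised spherical-law-of-cosines distance (m) between fixes i and j
# given precomputed radian coordinates; same convention as
# great_circle_km (sphere radius from the geodesy config).
fast_dist_m <- function(lam, phi, i, j, radius) {
  cosd <- sin(phi[i]) * sin(phi[j]) +
    cos(phi[i]) * cos(phi[j]) * cos(lam[j] - lam[i])
  radius * acos(pmin(1, pmax(-1, cosd)))
}

# Vectorised initial great-circle bearing (radians) from i to j.
fast_bearing <- function(lam, phi, i, j) {
  dl <- lam[j] - lam[i]
  atan2(sin(dl) * cos(phi[j]),
        cos(phi[i]) * sin(phi[j]) - sin(phi[i]) * cos(phi[j]) * cos(dl))
}

# Per-position RMS speed (m/s) of segments from each non-endpoint kept
# fix to its up-to-two preceding and succeeding kept neighbours.
# Endpoints get NA. Zero elapsed time counts as infinite speed unless
# the positions coincide.
kept_rms <- function(lam, phi, tt, kept, radius) {
  m <- length(kept)
  out <- rep(NA_real_, m)
  if (m < 3) return(out)
  sp <- function(off) {
    pos <- seq_len(m)
    nb <- pos + off
    ok <- nb >= 1 & nb <= m
    v <- rep(NA_real_, m)
    i <- kept[pos[ok]]; j <- kept[nb[ok]]
    d <- fast_dist_m(lam, phi, i, j, radius)
    dt <- abs(tt[j] - tt[i])
    vv <- d / dt
    vv[dt == 0] <- ifelse(d[dt == 0] == 0, 0, Inf)
    v[ok] <- vv
    v
  }
  v1 <- sp(-2); v2 <- sp(-1); v3 <- sp(1); v4 <- sp(2)
  s <- cbind(v1^2, v2^2, v3^2, v4^2)
  out <- sqrt(rowMeans(s, na.rm = TRUE))
  out[c(1, m)] <- NA
  out
}

# Per-position internal angle (deg) and adjacent step lengths (m) for
# kept fixes; endpoints NA.
kept_spikes <- function(lam, phi, kept, radius) {
  m <- length(kept)
  ang <- rep(NA_real_, m); d1 <- rep(NA_real_, m); d2 <- rep(NA_real_, m)
  if (m < 3) return(list(angle = ang, d_prev = d1, d_next = d2))
  pos <- 2:(m - 1)
  i0 <- kept[pos - 1]; i1 <- kept[pos]; i2 <- kept[pos + 1]
  d1[pos] <- fast_dist_m(lam, phi, i1, i0, radius)
  d2[pos] <- fast_dist_m(lam, phi, i1, i2, radius)
  b1 <- fast_bearing(lam, phi, i1, i0)
  b2 <- fast_bearing(lam, phi, i1, i2)
  a <- abs(b1 - b2) * 180 / pi
  a <- a %% 360
  a[a > 180] <- 360 - a[a > 180]
  a[d1[pos] == 0 | d2[pos] == 0] <- 180  # coincident: no spike
  ang[pos] <- a
  list(angle = ang, d_prev = d1, d_next = d2)
}

#' Speed-distance-angle filter for one bird's Argos fixes
#'
#' Cleans a time-sorted Argos track in three stages: (1) class-Z fixes
#' are dropped; (2) an iterative speed stage repeatedly removes the
#' non-endpoint fix with the largest root-mean-square of segment speeds
#' to its two preceding and two succeeding retained neighbours, while
#' that RMS exceeds `vmax` (ties broken to the later fix); (3) a spike
#' stage removes acute-angle out-and-back fixes per the angle/distance
#' thresholds, sharpest first. Stages 2-3 are iterated to a fixed
#' point, so the filter is idempotent. The first and last fixes are
#' never removed, and fixes are only ever removed, never relocated.
#'
#' @param fixes Tibble of one bird's fixes sorted by time
#'   (`bird_id`, `time`, `lon`, `lat`, `lc`).
#' @param config A [filter_config()].
#' @param geodesy A [geodesy_config()].
#' @return A list of class `filter_result`: `retained` (tibble, input
#'   order preserved), `removed` (tibble with a `reason` column, one of
#'   `"class_z"`, `"speed"`, `"spike"`), and `retention` (fraction kept).
#' @export
sda_filter <- function(fixes, config = filter_config(),
                       geodesy = geodesy_config()) {
  stopifnot(nrow(fixes) >= 1)
  if (length(unique(fixes$bird_id)) > 1)
    stop("sda_filter expects fixes of a single bird")
  if (is.unsorted(as.numeric(fixes$time)))
    stop("fixes must be sorted by time")

  n <- nrow(fixes)
  reason <- rep(NA_character_, n)
  lam <- fixes$lon * pi / 180
  phi <- fixes$lat * pi / 180
  tt <- as.numeric(fixes$time)
  R <- geodesy$earth_radius_m

  if (config$drop_class_z) reason[fixes$lc == "Z"] <- "class_z"
  kept <- which(is.na(reason))

  if (length(kept) >= 3) {
    repeat {
      changed <- FALSE
      repeat {  # speed stage
        rms <- kept_rms(lam, phi, tt, kept, R)
        worst <- suppressWarnings(max(rms, na.rm = TRUE))
        if (is.na(worst) || worst <= config$vmax) break
        at <- which(rms == worst)
        pos <- at[length(at)]  # later fix on ties
        reason[kept[pos]] <- "speed"
        kept <- kept[-pos]
        changed <- TRUE
        if (length(kept) < 3) break
      }
      repeat {  # spike stage
        if (length(kept) < 3) break
        ks <- kept_spikes(lam, phi, kept, R)
        hit <- rep(FALSE, length(kept))
        for (k in seq_along(config$spike_angles))
          hit <- hit | (!is.na(ks$angle) &
                        ks$angle < config$spike_angles[k] &
                        ks$d_prev > config$spike_dists[k] &
                        ks$d_next > config$spike_dists[k])
        if (!any(hit)) break
        cand <- which(hit)
        pos <- cand[ks$angle[cand] == min(ks$angle[cand])]
        pos <- pos[length(pos)]
        reason[kept[pos]] <- "spike"
        kept <- kept[-pos]
        changed <- TRUE
      }
      if (!changed) break
    }
  }

  retained <- fixes[is.na(reason), ]
  removed <- fixes[!is.na(reason), ]
  removed$reason <- reason[!is.na(reason)]
  structure(list(retained = retained, removed = removed,
                 retention = nrow(retained) / n),
            class = "filter_result")
}
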
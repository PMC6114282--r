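ARGOS_CLASSES <- c("3", "2", "1", "0", "A", "B", "Z")

#' Argos CSV dialect
#'
#' Maps the column names of a delimited Argos table onto the fields this
#' package expects, and states the timestamp format.
#'
#' @param id,time,lon,lat,lc Column names in the source file.
#' @param time_format A [strptime()] format; timestamps are parsed as UTC.
#' @param sep Field separator.
#' @return A list of class `argos_dialect`.
#' @export
argos_dialect <- function(id = "bird_id", time = "time", lon = "lon",
                          lat = "lat", lc = "lc",
                          time_format = "%Y-%m-%d %H:%M:%S", sep = ",") {
  structure(list(id = id, time = time, lon = lon, lat = lat, lc = lc,
                 time_format = time_format, sep = sep),
            class = "argos_dialect")
}

#' Read an Argos fix table
#'
#' Reads a delimited table of raw Argos uplinks, maps columns through a
#' dialect, validates each record (coordinate bounds, known location
#' class, parseable UTC timestamp), drops exact-duplicate rows, and
#' returns fixes sorted by bird and time. Invalid records are dropped
#' with a warning that lists their line numbers; the rejected rows are
#' attached as attribute `"rejected"`.
#'
#' @param path Path to a CSV/TSV file.
#' @param dialect An [argos_dialect()].
#' @return A tibble with columns `bird_id`, `time` (POSIXct UTC), `lon`,
#'   `lat`, `lc`, sorted by (bird_id, time).
#' @export
read_argos_table <- function(path, dialect = argos_dialect()) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c(dialect$id, dialect$time, dialect$lon, dialect$lat, dialect$lc)
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))

  line_no <- seq_len(nrow(raw)) + 1L  # header is line 1
  dup <- duplicated(raw[, need, drop = FALSE])
  raw <- raw[!dup, , drop = FALSE]; line_no <- line_no[!dup]

  tm <- as.POSIXct(raw[[dialect$time]], tz = "UTC",
                   format = dialect$time_format)
  lon <- suppressWarnings(as.numeric(raw[[dialect$lon]]))
  lat <- suppressWarnings(as.numeric(raw[[dialect$lat]]))
  lc <- toupper(trimws(raw[[dialect$lc]]))

  bad_time <- is.na(tm)
  bad_lon <- is.na(lon) | lon <= -180 | lon > 180
  bad_lat <- is.na(lat) | lat < -90 | lat > 90
  bad_lc <- !(lc %in% ARGOS_CLASSES)
  bad <- bad_time | bad_lon | bad_lat | bad_lc
  why <- ifelse(bad_time, "unparseable timestamp",
         ifelse(bad_lc, "unknown location class", "coordinate out of bounds"))
  if (any(bad)) {
    warning(sum(bad), " record(s) rejected (lines ",
            paste(line_no[bad], collapse = ", "), "): ",
            paste(unique(why[bad]), collapse = "; "))
  }
  out <- tibble::tibble(bird_id = raw[[dialect$id]][!bad],
                        time = tm[!bad], lon = lon[!bad], lat = lat[!bad],
                        lc = lc[!bad])
  rejected <- tibble::tibble(line = line_no[bad], reason = why[bad])
  out <- out[order(out$bird_id, out$time), ]
  attr(out, "rejected") <- rejected
  attr(out, "n_parsed") <- nrow(out)
  out
}

#' Write an Argos fix table
#'
#' Inverse of [read_argos_table()] for the package's default dialect;
#' reading the written file back reproduces the fixes.
#'
#' @param fixes Tibble as returned by [read_argos_table()].
#' @param path Output CSV path.
#' @export
write_argos_table <- function(fixes, path) {
  df <- data.frame(bird_id = fixes$bird_id,
                   time = format(fixes$time, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
                   lon = sprintf("%.9f", fixes$lon),
                   lat = sprintf("%.9f", fixes$lat),
                   lc = fixes$lc)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Coastline polyline
#'
#' A coastline is an ordered set of WGS84 vertices forming one or more
#' polylines; segment breaks are encoded by `NA` rows.
#'
#' @param lonlat Two-column matrix of vertices (lon, lat).
#' @return Object of class `coastline`.
#' @export
coastline <- function(lonlat) {
  lonlat <- rbind(lonlat)
  if (nrow(lonlat) < 2) stop("coastline needs at least 2 vertices")
  check_lonlat(lonlat[stats::complete.cases(lonlat), , drop = FALSE])
  structure(list(vertices = lonlat), class = "coastline")
}

#' Distance from points to a coastline, in km
#'
#' Minimum great-circle distance from each point to any coastline
#' segment.
#'
#' @param lonlat Two-column matrix of points.
#' @param coast A [coastline()].
#' @param geodesy A [geodesy_config()].
#' @return Numeric vector of distances in km.
#' @export
coast_distance_km <- function(lonlat, coast, geodesy = geodesy_config()) {
  if (is.null(coast)) stop("coastline required")
  lonlat <- rbind(lonlat)
  v <- coast$vertices[stats::complete.cases(coast$vertices), , drop = FALSE]
  d <- geosphere::dist2Line(lonlat, v, distfun = geosphere::distCosine)
  unname(d[, "distance"]) / 1000
}

#' Write trip outputs
#'
#' Writes the per-bird trip-summary table as CSV, daily tracks as a
#' GeoJSON FeatureCollection of LineStrings, and kernel isopleths as a
#' GeoJSON FeatureCollection of (Multi)Polygons. Field order is fixed so
#' output is deterministic.
#'
#' @param trips Trip-summary tibble (see [summarize_trip()]); may have
#'   zero rows.
#' @param daily Daily-position tibble or `NULL`.
#' @param kernels List of kernel results (see [kde_isopleths()]) or `NULL`.
#' @param dir Output directory, created if absent.
#' @return Invisibly, the paths written.
#' @export
write_trip_outputs <- function(trips, daily = NULL, kernels = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  p <- file.path(dir, "trips.csv")
  utils::write.csv(as.data.frame(trips), p, row.names = FALSE, na = "")
  paths <- c(paths, p)

  if (!is.null(daily)) {
    feats <- lapply(split(daily, daily$bird_id), function(d) {
      d <- d[order(d$date), ]
      list(type = "Feature",
           properties = list(bird_id = d$bird_id[1], n_days = nrow(d)),
           geometry = list(type = "LineString",
                           coordinates = unname(Map(c, d$lon, d$lat))))
    })
    p <- file.path(dir, "daily_tracks.geojson")
    jsonlite::write_json(list(type = "FeatureCollection",
                              features = unname(feats)),
                         p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }

  if (!is.null(kernels)) {
    feats <- list()
    for (k in kernels) {
      for (iso in k$isopleths) {
        rings <- lapply(iso$rings, function(r) unname(lapply(
          seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))))
        feats[[length(feats) + 1L]] <- list(
          type = "Feature",
          properties = list(phase = k$phase, quantile = iso$quantile,
                            area_km2 = iso$area_km2),
          geometry = list(type = "MultiPolygon",
                          coordinates = lapply(rings, list)))
      }
    }
    p <- file.path(dir, "isopleths.geojson")
    jsonlite::write_json(list(type = "FeatureCollection",
                              features = unname(feats)),
                         p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  invisible(paths)
}
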
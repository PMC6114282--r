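#' Kernel density configuration
#'
#' @param quantiles Isopleth quantiles in percent, strictly increasing,
#'   each in (0, 100). The q% isopleth is the smallest region containing
#'   q% of the utilization-distribution mass (percent-volume contour).
#' @param bandwidth_rule `"reference"` (Silverman's normal reference,
#'   per axis) or `"fixed"`.
#' @param fixed_bandwidth_km Bandwidth in km when `bandwidth_rule` is
#'   `"fixed"`.
#' @param grid_cell_km Evaluation grid resolution in km.
#' @param projection_center `c(lon, lat)` for the azimuthal-equidistant
#'   projection (normally the colony, so colony distances are
#'   undistorted).
#' @return A list of class `kernel_config`.
#' @export
kernel_config <- function(quantiles = c(20, 40, 60, 80),
                          bandwidth_rule = c("reference", "fixed"),
                          fixed_bandwidth_km = NULL, grid_cell_km = 25,
                          projection_center = c(168.188, -44.188)) {
  bandwidth_rule <- match.arg(bandwidth_rule)
  stopifnot(all(quantiles > 0), all(quantiles < 100),
            !is.unsorted(quantiles, strictly = TRUE), grid_cell_km > 0)
  if (bandwidth_rule == "fixed" && is.null(fixed_bandwidth_km))
    stop("fixed bandwidth rule needs fixed_bandwidth_km")
  structure(list(quantiles = quantiles, bandwidth_rule = bandwidth_rule,
                 fixed_bandwidth_km = fixed_bandwidth_km,
                 grid_cell_km = grid_cell_km,
                 projection_center = projection_center),
            class = "kernel_config")
}

#' Daily positions belonging to a journey phase
#'
#' Outward points are the daily positions between departure and reversal
#' (inclusive; the reversal day belongs to the outward phase) of birds
#' for which a reversal was determined; inward points are positions
#' between reversal and landfall of birds that reached mainland waters.
#' Birds without the phase-defining dates contribute nothing.
#'
#' @param trips Trip-summary tibble.
#' @param daily Daily-position tibble (all birds).
#' @param phase `"outward"` or `"inward"`.
#' @return Tibble of daily positions in the phase.
#' @export
phase_points <- function(trips, daily, phase = c("outward", "inward")) {
  phase <- match.arg(phase)
  out <- lapply(seq_len(nrow(trips)), function(i) {
    tr <- trips[i, ]
    d <- daily[daily$bird_id == tr$bird_id, , drop = FALSE]
    if (phase == "outward") {
      if (is.na(tr$reversal_date)) return(NULL)
      d[d$date >= tr$departure_date & d$date <= tr$reversal_date, ]
    } else {
      if (is.na(tr$landfall_date)) return(NULL)
      d[d$date > tr$reversal_date & d$date <= tr$landfall_date, ]
    }
  })
  dplyr::bind_rows(out)
}

silverman_bw <- function(x) {
  n <- length(x)
  1.06 * min(stats::sd(x), stats::IQR(x) / 1.34) * n^(-1 / 5)
}

#' Kernel utilization distribution and quantile isopleths
#'
#' Projects the points with an azimuthal-equidistant projection about
#' the configured center, evaluates a bivariate Gaussian kernel density
#' on a regular km grid (Silverman reference bandwidth per axis unless a
#' fixed bandwidth is given), and extracts, for each configured
#' quantile q, the smallest-area region containing q% of the total grid
#' mass: cell masses are sorted in decreasing order and accumulated
#' until q% is reached, and the threshold density defines the region.
#' Isopleths are nested by construction.
#'
#' @param points Tibble/data.frame with `lon`, `lat`.
#' @param config A [kernel_config()].
#' @param phase Label stored in the result.
#' @param geodesy A [geodesy_config()].
#' @return A list of class `kernel_result`: `phase`, `grid` (x/y cell
#'   centers in km, density matrix, cell area), `total_mass`, and
#'   `isopleths` — per quantile the threshold, contained mass fraction,
#'   area (km2), member cell indices and lon/lat polygon rings.
#' @export
kde_isopleths <- function(points, config = kernel_config(),
                          phase = "outward", geodesy = geodesy_config()) {
  stopifnot(nrow(points) >= 10)
  xy <- aeqd_project(cbind(points$lon, points$lat),
                     config$projection_center, geodesy)
  if (stats::sd(xy[, 1]) < 1e-9 && stats::sd(xy[, 2]) < 1e-9)
    stop("degenerate point set: all points identical")

  if (config$bandwidth_rule == "fixed") {
    h <- rep(config$fixed_bandwidth_km, 2)
  } else {
    h <- c(silverman_bw(xy[, 1]), silverman_bw(xy[, 2]))
    h[h <= 0] <- config$grid_cell_km
  }
  pad <- 4 * max(h)
  xr <- range(xy[, 1]) + c(-pad, pad)
  yr <- range(xy[, 2]) + c(-pad, pad)
  # keep at least ~4 cells per kernel sd so cell masses resolve the
  # quantile thresholds even for tight point clouds
  cx <- min(config$grid_cell_km, h[1] / 4)
  cy <- min(config$grid_cell_km, h[2] / 4)
  nx <- max(32L, ceiling(diff(xr) / cx))
  ny <- max(32L, ceiling(diff(yr) / cy))
  # MASS::kde2d's h is the full kernel width; its gaussian sd is h/4
  kd <- MASS::kde2d(xy[, 1], xy[, 2], h = 4 * h, n = c(nx, ny),
                    lims = c(xr, yr))
  cell_area <- diff(kd$x[1:2]) * diff(kd$y[1:2])
  mass <- kd$z * cell_area
  total <- sum(mass)

  ord <- order(kd$z, decreasing = TRUE)
  cum <- cumsum(mass[ord]) / total
  isopleths <- lapply(config$quantiles, function(q) {
    k <- which(cum >= q / 100)[1]
    thr <- kd$z[ord[k]]
    inside <- kd$z >= thr
    rings <- grDevices::contourLines(kd$x, kd$y, kd$z, levels = thr)
    rings <- lapply(rings, function(r) {
      ll <- aeqd_unproject(cbind(r$x, r$y), config$projection_center, geodesy)
      ll
    })
    list(quantile = q, threshold = thr,
         mass_fraction = sum(mass[inside]) / total,
         area_km2 = sum(inside) * cell_area,
         cells = which(inside), rings = rings)
  })
  structure(list(phase = phase,
                 grid = list(x = kd$x, y = kd$y, z = kd$z,
                             cell_area_km2 = cell_area),
                 bandwidth_km = h, total_mass = total,
                 isopleths = isopleths),
            class = "kernel_result")
}
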
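#' Simulate a synthetic environmental stack
#'
#' Generates co-registered layers with the qualitative structure of the
#' southern Tasman Sea fields used for habitat selection: SST as a
#' smooth north-south gradient with two front-like steps (the
#' subtropical and subantarctic fronts), chlorophyll-a as random patches
#' optionally elevated along the northern front, sea-level anomaly as a
#' field of Gaussian eddies, current speed as the SLA spatial-gradient
#' magnitude, bathymetry as a deep basin with a ridge/seamount chain,
#' and a smooth mixed-layer depth. With `coupling = FALSE` the layers
#' are mutually independent.
#'
#' @param grid A [grid_spec()] (projected km about the colony).
#' @param seed RNG seed.
#' @param coupling Couple CHLA to the northern SST front?
#' @param n_eddies Number of SLA eddies.
#' @param eddy_amplitude_m Peak eddy amplitude (m); 0 gives a flat SLA
#'   and identically-zero current speed.
#' @param front_lats_km y-positions (km, in the projected plane) of the
#'   two SST fronts.
#' @param constant Named list of layers to hold spatially constant
#'   (value = the constant), for degenerate-input tests.
#' @return List with the [env_stack()] (`stack`) and `truth` (front
#'   positions, eddy table).
#' @export
simulate_env <- function(grid = grid_spec(), seed = 1, coupling = TRUE,
                         n_eddies = 12, eddy_amplitude_m = 0.25,
                         front_lats_km = c(-900, -1600),
                         constant = list()) {
  set.seed(seed)
  gx <- grid_x(grid); gy <- grid_y(grid)
  X <- matrix(gx, grid$nx, grid$ny)
  Y <- matrix(gy, grid$nx, grid$ny, byrow = TRUE)

  # SST: ~16 C at the colony latitude falling south, two tanh fronts
  sst <- 14 + 0.004 * Y - 2.5 * (1 + tanh((front_lats_km[1] - Y) / 120)) -
    2.0 * (1 + tanh((front_lats_km[2] - Y) / 150)) +
    0.3 * sin(X / 700) + stats::rnorm(length(X), 0, 0.1)

  # CHLA: lognormal patches; coupling elevates a band at the first front
  n_patch <- 60
  px <- stats::runif(n_patch, min(gx), max(gx))
  py <- stats::runif(n_patch, min(gy), max(gy))
  ps <- stats::runif(n_patch, 60, 150)
  pa <- stats::rlnorm(n_patch, log(0.22), 0.35)
  chla <- matrix(0.15, grid$nx, grid$ny)
  for (k in seq_len(n_patch))
    chla <- chla + pa[k] * exp(-((X - px[k])^2 + (Y - py[k])^2) / (2 * ps[k]^2))
  if (coupling)
    chla <- chla + 0.6 * exp(-(Y - front_lats_km[1])^2 / (2 * 150^2))

  # SLA: Gaussian eddies of either sign
  ex <- stats::runif(n_eddies, min(gx), max(gx))
  ey <- stats::runif(n_eddies, min(gy), max(gy))
  es <- stats::runif(n_eddies, 60, 160)
  ea <- eddy_amplitude_m * stats::runif(n_eddies, 0.4, 1) *
    sample(c(-1, 1), n_eddies, replace = TRUE)
  sla <- matrix(0, grid$nx, grid$ny)
  for (k in seq_len(n_eddies))
    sla <- sla + ea[k] * exp(-((X - ex[k])^2 + (Y - ey[k])^2) / (2 * es[k]^2))

  # CURR: geostrophic-like speed from the SLA gradient magnitude
  curr <- matrix(0, grid$nx, grid$ny)
  if (grid$nx >= 3 && grid$ny >= 3) {
    dx <- (sla[c(2:grid$nx, grid$nx), ] - sla[c(1, 1:(grid$nx - 1)), ]) /
      (2 * grid$cell_km)
    dy <- (sla[, c(2:grid$ny, grid$ny)] - sla[, c(1, 1:(grid$ny - 1))]) /
      (2 * grid$cell_km)
    curr <- 150 * sqrt(dx^2 + dy^2)   # ~0.1-0.5 m/s for default eddies
  }

  # BATHY: deep basin with a SW-trending ridge and seamounts (no shared
  # latitudinal trend, so uncoupled layers stay mutually independent)
  bathy <- -4500 +
    2500 * exp(-((X * cos(0.7) + Y * sin(0.7)) -
                   (-300))^2 / (2 * 180^2))
  n_smt <- 6
  sx <- stats::runif(n_smt, min(gx), max(gx))
  sy <- stats::runif(n_smt, min(gy), max(gy))
  for (k in seq_len(n_smt))
    bathy <- bathy + 1800 * exp(-((X - sx[k])^2 + (Y - sy[k])^2) / (2 * 70^2))
  bathy <- pmin(bathy, -10)

  # MLD: smooth undulation from several random plane waves whose
  # wavelengths (500-1000 km) fit many periods in the domain, so no
  # mode aliases the meridional SST trend or the single ridge structure
  mld <- matrix(55, grid$nx, grid$ny)
  for (m in 1:8) {
    wl <- stats::runif(1, 500, 1000)
    th <- stats::runif(1, 0, 2 * pi)
    phm <- stats::runif(1, 0, 2 * pi)
    mld <- mld + stats::runif(1, 3, 5) *
      sin(2 * pi * (X * cos(th) + Y * sin(th)) / wl + phm)
  }

  layers <- list(BATHY = bathy,
                 SLOPE = derive_slope(bathy, grid$cell_km),
                 SST = sst, CHLA = chla, CURR = curr, SLA = sla, MLD = mld)
  for (nm in names(constant))
    layers[[nm]] <- matrix(constant[[nm]], grid$nx, grid$ny)

  truth <- list(front_lats_km = front_lats_km,
                eddies = tibble::tibble(x = ex, y = ey, sd_km = es,
                                        amp_m = ea),
                coupling = coupling)
  list(stack = env_stack(grid, layers,
                         windows = list(default = "32-day composite",
                                        SLA = "mean of 5-day composites",
                                        MLD = "static climatology")),
       truth = truth)
}
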
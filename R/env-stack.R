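#' Equal-area analysis grid
#'
#' A regular grid in the azimuthal-equidistant plane about a center
#' (planar km coordinates), used as the common grid onto which all
#' environmental layers are resampled. The default 57.4 km cell size is
#' the lowest common resolution of the source products (set by the
#' mixed-layer-depth climatology).
#'
#' @param center `c(lon, lat)` of the projection center.
#' @param cell_km Cell size in km (> 0).
#' @param nx,ny Number of cells east/north.
#' @param x0,y0 Cell-center coordinates (km) of cell \[1, 1\]; default
#'   centers the grid on the projection center.
#' @return A list of class `grid_spec`.
#' @export
grid_spec <- function(center = c(168.188, -44.188), cell_km = 57.4,
                      nx = 60, ny = 60,
                      x0 = -(nx - 1) / 2 * cell_km,
                      y0 = -(ny - 1) / 2 * cell_km) {
  stopifnot(cell_km > 0, nx >= 1, ny >= 1)
  structure(list(center = center, cell_km = cell_km, nx = as.integer(nx),
                 ny = as.integer(ny), x0 = x0, y0 = y0),
            class = "grid_spec")
}

grid_x <- function(g) g$x0 + (seq_len(g$nx) - 1) * g$cell_km
grid_y <- function(g) g$y0 + (seq_len(g$ny) - 1) * g$cell_km

same_grid <- function(a, b) {
  isTRUE(all.equal(a$center, b$center)) && a$cell_km == b$cell_km &&
    a$nx == b$nx && a$ny == b$ny && a$x0 == b$x0 && a$y0 == b$y0
}

#' Environmental layer stack
#'
#' Named co-registered layers on one [grid_spec()]. Layers are `nx * ny`
#' matrices indexed \[ix, iy\]; missing cells are `NA` (masked), never
#' zero-filled. Conventional keys: `BATHY` (depth, m, negative down),
#' `SLOPE` (m/km), `SST` (deg C), `CHLA` (mg/m3), `CURR` (m/s), `SLA`
#' (m), `MLD` (m).
#'
#' @param grid A [grid_spec()].
#' @param layers Named list of matrices with `dim = c(nx, ny)`.
#' @param windows Optional named list of time-window metadata per layer.
#' @return A list of class `env_stack`.
#' @export
env_stack <- function(grid, layers, windows = NULL) {
  stopifnot(inherits(grid, "grid_spec"), length(layers) >= 1,
            !is.null(names(layers)))
  for (nm in names(layers))
    if (!all(dim(layers[[nm]]) == c(grid$nx, grid$ny)))
      stop("layer ", nm, " does not match the grid dimensions")
  structure(list(grid = grid, layers = layers, windows = windows),
            class = "env_stack")
}

#' Cell-wise temporal composite of layers
#'
#' Arithmetic mean over a list of co-registered layers (e.g. the
#' five-day sea-level-anomaly fields spanning a 32-day window), ignoring
#' masked cells; a cell masked in every layer stays masked.
#'
#' @param layers Non-empty list of matrices of identical dimension.
#' @return A single matrix.
#' @export
composite_layers <- function(layers) {
  if (!length(layers)) stop("empty compositing window")
  d <- dim(layers[[1]])
  for (l in layers) stopifnot(all(dim(l) == d))
  a <- array(unlist(layers), dim = c(d, length(layers)))
  out <- apply(a, c(1, 2), function(v)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  out
}

#' Seafloor slope from bathymetry
#'
#' Gradient magnitude of a bathymetry layer by Horn's 3x3 operator, in
#' meters of depth change per km of horizontal distance. Border cells
#' (and cells with a masked neighbour) are masked.
#'
#' @param bathy Bathymetry matrix (m, negative down) on a projected grid.
#' @param cell_km Grid cell size in km.
#' @return Slope matrix (m/km).
#' @export
derive_slope <- function(bathy, cell_km) {
  nx <- nrow(bathy); ny <- ncol(bathy)
  if (nx < 3 || ny < 3) stop("grid too small for slope (need >= 3x3)")
  out <- matrix(NA_real_, nx, ny)
  z <- bathy
  for (i in 2:(nx - 1)) for (j in 2:(ny - 1)) {
    w <- z[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (anyNA(w)) next
    dzdx <- ((w[3, 1] + 2 * w[3, 2] + w[3, 3]) -
             (w[1, 1] + 2 * w[1, 2] + w[1, 3])) / (8 * cell_km)
    dzdy <- ((w[1, 3] + 2 * w[2, 3] + w[3, 3]) -
             (w[1, 1] + 2 * w[2, 1] + w[3, 1])) / (8 * cell_km)
    out[i, j] <- sqrt(dzdx^2 + dzdy^2)
  }
  out
}

#' Surface current speed from velocity components
#'
#' @param u,v Co-registered eastward/northward velocity matrices (m/s).
#' @return Speed matrix, `sqrt(u^2 + v^2)`.
#' @export
current_speed <- function(u, v) {
  if (!all(dim(u) == dim(v))) stop("u and v grids do not match")
  sqrt(u^2 + v^2)
}

# Bilinear/nearest sampling of one native layer at target points (km).
sample_layer <- function(values, native, xq, yq, rule) {
  gx <- grid_x(native); gy <- grid_y(native)
  n <- length(xq)
  out <- rep(NA_real_, n)
  if (rule == "nearest") {
    ix <- round((xq - native$x0) / native$cell_km) + 1
    iy <- round((yq - native$y0) / native$cell_km) + 1
    ok <- ix >= 1 & ix <= native$nx & iy >= 1 & iy <= native$ny
    out[ok] <- values[cbind(ix[ok], iy[ok])]
    return(out)
  }
  fx <- (xq - native$x0) / native$cell_km
  fy <- (yq - native$y0) / native$cell_km
  i0 <- floor(fx) + 1; j0 <- floor(fy) + 1
  ok <- i0 >= 1 & i0 + 1 <= native$nx & j0 >= 1 & j0 + 1 <= native$ny
  wx <- fx - floor(fx); wy <- fy - floor(fy)
  for (k in which(ok)) {
    q <- values[i0[k]:(i0[k] + 1), j0[k]:(j0[k] + 1)]
    if (anyNA(q)) next  # propagate masks
    out[k] <- (1 - wx[k]) * (1 - wy[k]) * q[1, 1] +
              wx[k] * (1 - wy[k]) * q[2, 1] +
              (1 - wx[k]) * wy[k] * q[1, 2] +
              wx[k] * wy[k] * q[2, 2]
  }
  out
}

#' Resample layers onto a common grid
#'
#' Resamples native-resolution layers (each a list with its own
#' `grid_spec` and `values` matrix, sharing the projection center) onto
#' the target grid by bilinear (default) or nearest-neighbour sampling
#' at the target cell centers. Masked native cells propagate; target
#' cells outside a native extent are masked; a layer with no spatial
#' overlap is an error.
#'
#' @param native_layers Named list of `list(grid = grid_spec, values =
#'   matrix)` entries.
#' @param grid Target [grid_spec()].
#' @param rule `"bilinear"` or `"nearest"`.
#' @param windows Optional time-window metadata passed through.
#' @return An [env_stack()] on the target grid.
#' @export
resample_to_grid <- function(native_layers, grid,
                             rule = c("bilinear", "nearest"),
                             windows = NULL) {
  rule <- match.arg(rule)
  pts <- expand.grid(x = grid_x(grid), y = grid_y(grid))
  layers <- lapply(names(native_layers), function(nm) {
    nl <- native_layers[[nm]]
    if (!isTRUE(all.equal(nl$grid$center, grid$center)))
      stop("layer ", nm, ": projection centers differ")
    v <- sample_layer(nl$values, nl$grid, pts$x, pts$y, rule)
    if (all(is.na(v))) stop("layer ", nm, ": no spatial overlap with grid")
    matrix(v, grid$nx, grid$ny)
  })
  names(layers) <- names(native_layers)
  env_stack(grid, layers, windows)
}

#' Grid cell index of projected points
#'
#' @param lonlat Two-column matrix of points.
#' @param grid A [grid_spec()].
#' @param geodesy A [geodesy_config()].
#' @return Integer vector of linear cell indices (NA outside the grid).
#' @export
cell_of <- function(lonlat, grid, geodesy = geodesy_config()) {
  xy <- aeqd_project(rbind(lonlat), grid$center, geodesy)
  ix <- round((xy[, 1] - grid$x0) / grid$cell_km) + 1
  iy <- round((xy[, 2] - grid$y0) / grid$cell_km) + 1
  ok <- ix >= 1 & ix <= grid$nx & iy >= 1 & iy <= grid$ny
  out <- rep(NA_integer_, nrow(xy))
  out[ok] <- as.integer(ix[ok] + (iy[ok] - 1) * grid$nx)
  out
}
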
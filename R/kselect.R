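#' Habitat-selection configuration
#'
#' @param window_days Days each side of the trip reversal defining the
#'   destination window.
#' @param availability_radius_km Radius of the availability disc around
#'   each bird's destination-window centroid, km.
#' @param composite_days Temporal compositing window for most layers,
#'   days.
#' @param sla_composite_days Native composite length of sea-level
#'   anomaly fields, days.
#' @param n_axes Factorial axes retained for reporting.
#' @param resample_rule `"bilinear"` or `"nearest"`.
#' @return A list of class `habitat_config`.
#' @export
habitat_config <- function(window_days = 10, availability_radius_km = 300,
                           composite_days = 32, sla_composite_days = 5,
                           n_axes = 2,
                           resample_rule = c("bilinear", "nearest")) {
  resample_rule <- match.arg(resample_rule)
  stopifnot(window_days > 0, availability_radius_km > 0, composite_days > 0,
            sla_composite_days > 0, n_axes >= 1)
  structure(list(window_days = window_days,
                 availability_radius_km = availability_radius_km,
                 composite_days = composite_days,
                 sla_composite_days = sla_composite_days,
                 n_axes = n_axes, resample_rule = resample_rule),
            class = "habitat_config")
}

#' Daily positions in a bird's destination window
#'
#' The positions within `window_days` days either side of the trip
#' reversal date; birds without a reversal are excluded with a warning.
#'
#' @param trip One-row trip summary.
#' @param daily Daily positions of the same bird.
#' @param config A [habitat_config()].
#' @return Tibble of daily positions (possibly with gaps), or a zero-row
#'   tibble if the bird has no reversal.
#' @export
destination_window_points <- function(trip, daily,
                                      config = habitat_config()) {
  if (is.na(trip$reversal_date)) {
    warning("bird ", trip$bird_id, " has no reversal date; excluded")
    return(daily[0, ])
  }
  d <- daily[daily$bird_id == trip$bird_id, , drop = FALSE]
  d[abs(as.numeric(d$date - trip$reversal_date)) <= config$window_days, ]
}

#' Availability cells around a destination
#'
#' All grid cells whose centers lie within `availability_radius_km` of
#' the centroid of a bird's destination-window positions.
#'
#' @param window_points Tibble from [destination_window_points()].
#' @param grid A [grid_spec()].
#' @param config A [habitat_config()].
#' @param geodesy A [geodesy_config()].
#' @return Integer vector of linear cell indices.
#' @export
availability_cells <- function(window_points, grid,
                               config = habitat_config(),
                               geodesy = geodesy_config()) {
  stopifnot(nrow(window_points) >= 1)
  ctr <- geographic_mean(cbind(window_points$lon, window_points$lat))
  cxy <- aeqd_project(rbind(ctr), grid$center, geodesy)
  gx <- grid_x(grid); gy <- grid_y(grid)
  pts <- expand.grid(x = gx, y = gy)
  d <- sqrt((pts$x - cxy[1])^2 + (pts$y - cxy[2])^2)
  which(d <= config$availability_radius_km)
}

#' K-select eigenanalysis of habitat selection
#'
#' Each animal's habitat selection is summarised by its marginality
#' vector: the difference between the mean environmental conditions it
#' used and the mean conditions available to it, in standardized
#' variable space. The analysis is a weighted non-centred principal
#' component analysis of these vectors: it eigen-decomposes
#' `sum_k lambda_k m_k m_k'`, so the eigenvalues measure the mean
#' squared marginality carried by each factorial axis, and if all
#' animals selected habitat alike, all vectors point the same way along
#' axis 1.
#'
#' Variables are standardized to zero weighted mean and unit weighted
#' variance over the union of availability sets (each animal's
#' availability contributing with its weight), so loadings are
#' comparable across units. Weights default to the number of
#' relocations per animal, normalized to sum 1. Note the depth layer
#' (`BATHY`) is negative downward, so a preference for shallow water is
#' a positive marginality on that variable.
#'
#' @param used List (per animal) of integer cell indices actually used;
#'   multiple relocations in one cell repeat the index (usage
#'   intensity).
#' @param available List (per animal) of integer cell indices available;
#'   must contain the animal's used cells.
#' @param stack An [env_stack()]; cells masked in any layer are dropped
#'   from both designs.
#' @param weights Optional per-animal weights; default relocation
#'   counts.
#' @return A list of class `kselect_result`: `variables`, `weights`,
#'   `eigenvalues`, `loadings` (variables x axes), `marginality`
#'   (animals x variables, standardized), `projections` (animals x
#'   axes), `avail_proj` and `used_proj` (arrow base/tip for the raw
#'   display), `recentred` (= `projections`, availability at origin).
#' @export
kselect <- function(used, available, stack, weights = NULL) {
  stopifnot(length(used) == length(available), length(used) >= 2)
  vars <- names(stack$layers)
  n <- length(used)
  if (is.null(names(used))) names(used) <- paste0("animal", seq_len(n))

  V <- sapply(stack$layers, function(m) as.numeric(m))  # ncell x p
  valid <- which(stats::complete.cases(V))

  avail <- lapply(available, function(a) intersect(a, valid))
  usd <- lapply(used, function(u) u[u %in% valid])
  for (k in seq_len(n)) {
    if (!length(usd[[k]]) || !length(avail[[k]]))
      stop("animal ", names(used)[k], ": no unmasked cells")
    if (!all(usd[[k]] %in% avail[[k]]))
      stop("animal ", names(used)[k], ": used cells outside availability")
  }

  if (is.null(weights)) weights <- vapply(usd, length, numeric(1))
  stopifnot(length(weights) == n, all(weights > 0))
  lambda <- weights / sum(weights)

  # weighted standardization over the union of availability sets
  p <- length(vars)
  wsum <- 0; mu <- rep(0, p); m2 <- rep(0, p)
  for (k in seq_len(n)) {
    w <- lambda[k] / length(avail[[k]])
    Vk <- V[avail[[k]], , drop = FALSE]
    wsum <- wsum + lambda[k]
    mu <- mu + w * colSums(Vk)
    m2 <- m2 + w * colSums(Vk^2)
  }
  mu <- mu / wsum
  sig2 <- m2 / wsum - mu^2
  if (any(sig2 <= 1e-12))
    stop("zero variance over availability for variable(s): ",
         paste(vars[sig2 <= 1e-12], collapse = ", "))
  sig <- sqrt(sig2)

  std <- function(idx) sweep(sweep(V[idx, , drop = FALSE], 2, mu), 2, sig, "/")
  avail_means <- t(vapply(avail, function(a) colMeans(std(a)), numeric(p)))
  used_means <- t(vapply(usd, function(u) colMeans(std(u)), numeric(p)))
  M <- used_means - avail_means
  rownames(M) <- names(used); colnames(M) <- vars

  S <- crossprod(M * sqrt(lambda))          # sum_k lambda_k m_k m_k'
  eg <- eigen(S, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  U <- eg$vectors
  rownames(U) <- vars; colnames(U) <- paste0("axis", seq_len(p))

  structure(list(
    variables = vars, weights = lambda, eigenvalues = ev, loadings = U,
    marginality = M, projections = M %*% U,
    avail_proj = avail_means %*% U, used_proj = used_means %*% U,
    recentred = M %*% U,
    standardization = list(mean = stats::setNames(mu, vars),
                           sd = stats::setNames(sig, vars))),
    class = "kselect_result")
}

#' Randomization test of per-animal marginality
#'
#' For each animal, the squared marginality norm is compared with its
#' null distribution obtained by resampling the animal's used cells
#' uniformly from its availability set.
#'
#' @inheritParams kselect
#' @param n_perm Number of permutations.
#' @param seed RNG seed.
#' @return Tibble with per-animal observed squared marginality and
#'   permutation p-value.
#' @export
kselect_randomization <- function(used, available, stack, weights = NULL,
                                  n_perm = 199, seed = 1) {
  set.seed(seed)
  obs <- kselect(used, available, stack, weights)
  stat <- rowSums(obs$marginality^2)
  pvals <- vapply(seq_along(used), function(k) {
    nk <- length(used[[k]])
    null <- vapply(seq_len(n_perm), function(r) {
      u2 <- used
      u2[[k]] <- sample(available[[k]], nk, replace = TRUE)
      sum(kselect(u2, available, stack, weights)$marginality[k, ]^2)
    }, numeric(1))
    (1 + sum(null >= stat[k])) / (n_perm + 1)
  }, numeric(1))
  tibble::tibble(animal = rownames(obs$marginality),
                 marginality_sq = stat, p = pvals)
}
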
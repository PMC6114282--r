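#' Linear mixed-effects model of a trip parameter
#'
#' Fits `response ~ destination + sex + (1 | bird)` with reference
#' levels SAF (destination) and female (sex), as used for the published
#' trip-parameter models. Duration and trip length are restricted to
#' complete trips; all responses require destination and sex to be
#' known. Date responses are converted to day offsets from `date_origin`
#' before fitting and the intercept is back-converted to a date (the
#' origin cancels in the effect estimates).
#'
#' Because each bird contributes a single observation, the fixed-effect
#' estimates coincide with ordinary least squares on the same design and
#' the bird-level variance decomposition is not identifiable; the fit is
#' flagged accordingly and no variance split is reported.
#'
#' @param trips Trip-summary tibble (e.g. [table1_as_trips()] or rows
#'   from [summarize_trip()]).
#' @param response One of `"departure_date"`, `"max_range_km"`,
#'   `"daily_km_median"`, `"duration_days"`, `"trip_length_km"`.
#' @param date_origin Origin for the Julian transformation of date
#'   responses.
#' @return A list of class `trip_model_fit`: `response`, `n`,
#'   `coefficients` (tibble with term/estimate/se/df/t/p),
#'   `intercept_date` (for date responses), `variance_identifiable`
#'   (FALSE), and the underlying `nlme::lme` fit.
#' @export
fit_trip_lmm <- function(trips, response, date_origin = as.Date("2016-11-01")) {
  responses <- c("departure_date", "max_range_km", "daily_km_median",
                 "duration_days", "trip_length_km")
  response <- match.arg(response, responses)

  d <- trips[!is.na(trips$destination) & !is.na(trips$sex), , drop = FALSE]
  if (response %in% c("duration_days", "trip_length_km"))
    d <- d[d$status == "complete", , drop = FALSE]

  y <- d[[response]]
  is_date <- inherits(y, "Date")
  if (is_date) y <- as.numeric(y - date_origin)
  keep <- !is.na(y)
  d <- d[keep, , drop = FALSE]; y <- y[keep]

  for (lev in c("SAF", "STF"))
    if (!lev %in% d$destination) stop("destination level absent: ", lev)
  for (lev in c("female", "male"))
    if (!lev %in% d$sex) stop("sex level absent: ", lev)

  df <- data.frame(y = y,
                   destination = factor(d$destination, c("SAF", "STF")),
                   sex = factor(d$sex, c("female", "male")),
                   bird = factor(d$bird_id))
  # one observation per bird: if the (unidentifiable) variance split
  # defeats the optimiser, the fixed effects are still exactly the
  # least-squares solution, so fall back to that
  fit <- tryCatch(
    nlme::lme(y ~ destination + sex, random = ~ 1 | bird, data = df,
              method = "REML"),
    error = function(e) stats::lm(y ~ destination + sex, data = df))
  if (inherits(fit, "lme")) {
    tt <- summary(fit)$tTable
    coefs <- tibble::tibble(
      term = c("Intercept", "Front (STF)", "Sex (Male)"),
      estimate = unname(tt[, "Value"]), se = unname(tt[, "Std.Error"]),
      df = unname(tt[, "DF"]), t = unname(tt[, "t-value"]),
      p = unname(tt[, "p-value"]))
  } else {
    # a perfectly collinear/constant response makes t and p meaningless
    sm <- suppressWarnings(summary(fit))$coefficients
    coefs <- tibble::tibble(
      term = c("Intercept", "Front (STF)", "Sex (Male)"),
      estimate = unname(sm[, 1]), se = unname(sm[, 2]),
      df = rep(nrow(df) - 3, 3), t = unname(sm[, 3]),
      p = unname(sm[, 4]))
  }

  structure(list(
    response = response, n = nrow(df), coefficients = coefs,
    intercept_date = if (is_date)
      date_origin + round(coefs$estimate[1]) else as.Date(NA),
    date_origin = if (is_date) date_origin else as.Date(NA),
    variance_identifiable = FALSE, fit = fit),
    class = "trip_model_fit")
}

#' Closed-form least-squares solve for the same design
#'
#' Normal-equations solution of `y ~ destination + sex` (reference SAF,
#' female). With one observation per bird this is the exact fixed-effect
#' solution of the mixed model, and serves as its independent oracle.
#'
#' @inheritParams fit_trip_lmm
#' @return Named numeric vector of the three fixed effects.
#' @export
ols_trip_solve <- function(trips, response,
                           date_origin = as.Date("2016-11-01")) {
  d <- trips[!is.na(trips$destination) & !is.na(trips$sex), , drop = FALSE]
  if (response %in% c("duration_days", "trip_length_km"))
    d <- d[d$status == "complete", , drop = FALSE]
  y <- d[[response]]
  if (inherits(y, "Date")) y <- as.numeric(y - date_origin)
  d <- d[!is.na(y), , drop = FALSE]; y <- y[!is.na(y)]
  X <- cbind(1, d$destination == "STF", d$sex == "male")
  beta <- solve(crossprod(X), crossprod(X, y))
  stats::setNames(as.numeric(beta), c("Intercept", "Front (STF)", "Sex (Male)"))
}

#' Travel-rate smooth over relative trip time
#'
#' Penalised cubic-spline smooth of daily travel distance (km/day)
#' against relative trip time in \[0, 1\], with a bird-level random
#' intercept; smoothness is selected by REML. Captures how birds ramp
#' their daily travel quota up over the course of the journey.
#'
#' @param km_day Daily travel distances (km/day).
#' @param rel_time Relative trip time in \[0, 1\], same length.
#' @param bird_id Bird identifier per observation.
#' @param k Spline basis dimension.
#' @return A list of class `travel_rate_fit` with the `mgcv::gam` fit,
#'   bird-level random intercepts, and `curve(t)`, a function returning
#'   the population-mean fitted values (with standard errors) at any t.
#' @export
fit_travel_rate <- function(km_day, rel_time, bird_id, k = 10) {
  stopifnot(length(km_day) == length(rel_time),
            length(km_day) == length(bird_id))
  ok <- stats::complete.cases(km_day, rel_time, bird_id)
  km_day <- km_day[ok]; rel_time <- rel_time[ok]; bird_id <- bird_id[ok]
  if (length(km_day) < 10) stop("need at least 10 observations")
  if (length(unique(bird_id)) < 2) stop("need at least 2 birds")
  df <- data.frame(y = km_day, t = rel_time, bird = factor(bird_id))
  fit <- mgcv::gam(y ~ s(t, bs = "cs", k = k) + s(bird, bs = "re"),
                   data = df, method = "REML")
  b0 <- levels(df$bird)[1]
  curve <- function(t) {
    nd <- data.frame(t = t, bird = factor(b0, levels = levels(df$bird)))
    pr <- mgcv::predict.gam(fit, nd, se.fit = TRUE, exclude = "s(bird)",
                            newdata.guaranteed = TRUE)
    tibble::tibble(t = t, fit = as.numeric(pr$fit),
                   se = as.numeric(pr$se.fit))
  }
  re <- tryCatch({
    cf <- stats::coef(fit)
    unname(cf[grep("^s\\(bird\\)", names(cf))])
  }, error = function(e) numeric(0))
  structure(list(fit = fit, curve = curve, random_intercepts = re,
                 n = nrow(df), n_birds = length(unique(bird_id))),
            class = "travel_rate_fit")
}
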
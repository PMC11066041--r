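#' Ground-truth exposure-lag-response surface
#'
#' A known log-RR surface f(x, l) used to seed synthetic panels so that the
#' whole pipeline can be checked by parameter recovery. The default family
#' is a product form f(x, l) = (g(x) - g(x_ref)) * w(l): an inverted-U
#' quadratic in exposure, peaking near 40 ug/m3 (the concentration where
#' mid-range particulate levels are most strongly associated with admission
#' risk in Korean respiratory series), times a geometric lag decay w(l)
#' proportional to decay^l, normalized to sum to 1 over lags 0..max_lag so
#' the cumulative effect equals g(x) - g(x_ref). The surface is exactly
#' zero at x_ref for every lag.
#'
#' @param family Surface family; only `"invu_geometric"` and `"null"` are
#'   provided.
#' @param max_lag Integer true maximum lag L (days).
#' @param x_ref Reference exposure (ug/m3) where f vanishes.
#' @param peak Exposure (ug/m3) at which the inverted-U peaks.
#' @param width Half-width scale of the quadratic (ug/m3).
#' @param amplitude Log-RR at the peak relative to g = 0 (i.e. g(peak)).
#' @param decay Geometric decay rate of the lag weights, in (0, 1).
#' @return An object of class `true_surface` with an `eval(x, l)` closure.
#' @export
true_surface <- function(family = c("invu_geometric", "null"),
                         max_lag = 14L, x_ref = 45,
                         peak = 40, width = 30, amplitude = 0.08,
                         decay = 0.7) {
  family <- match.arg(family)
  max_lag <- as.integer(max_lag)
  stopifnot(max_lag >= 0)
  if (family == "null") {
    fun <- function(x, l) rep(0, length(x))
    params <- list()
  } else {
    stopifnot(decay > 0, decay < 1, width > 0)
    w <- decay^(0:max_lag)
    w <- w / sum(w)
    g <- function(x) amplitude * (1 - ((x - peak) / width)^2)
    g_ref <- g(x_ref)
    fun <- function(x, l) {
      out <- (g(x) - g_ref) * w[pmin(l, max_lag) + 1L]
      out[l > max_lag] <- 0
      out
    }
    params <- list(peak = peak, width = width, amplitude = amplitude, decay = decay)
  }
  structure(
    list(family = family, params = params, max_lag = max_lag, x_ref = x_ref,
         eval = fun),
    class = "true_surface"
  )
}

#' Evaluate a true surface
#' @param surface A `true_surface`.
#' @param x Exposure values.
#' @param l Lag values (recycled against `x`).
#' @return Log-RR contributions f(x, l).
#' @export
surface_eval <- function(surface, x, l) {
  stopifnot(inherits(surface, "true_surface"))
  n <- max(length(x), length(l))
  surface$eval(rep_len(x, n), rep_len(l, n))
}

#' Cumulative true log-RR over the full lag window
#'
#' Sum of f(x, l) over l = 0..max_lag, re-referenced at `x_ref` (defaults to
#' the surface's own reference).
#' @param surface A `true_surface`.
#' @param x Exposure values.
#' @param x_ref Reference exposure.
#' @return Cumulative log-RR at each `x`.
#' @export
surface_cumulative <- function(surface, x, x_ref = surface$x_ref) {
  lags <- 0:surface$max_lag
  cum <- vapply(x, function(xx) sum(surface$eval(rep(xx, length(lags)), lags)),
                numeric(1))
  ref <- sum(surface$eval(rep(x_ref, length(lags)), lags))
  cum - ref
}

#' Simulation configuration for synthetic multi-city panels
#'
#' Defaults emulate a Korean metropolitan daily admissions panel: PM10-like
#' pollutant around 45 ug/m3 with winter-peaking seasonality and AR(1)
#' persistence, about twenty admissions per city-day with mild annual
#' seasonality and overdispersion, and five mutually independent seasonal
#' meteorological covariates.
#'
#' @param n_cities Number of cities.
#' @param start_date,end_date Calendar dates (coerced by `as.Date`).
#' @param baseline_log_rate Per-city log baseline admission rate (recycled).
#' @param seasonal_amplitude Amplitudes of the annual harmonics of the log
#'   admission rate (first element = first harmonic, etc.).
#' @param gamma Named covariate log-rate slopes over
#'   (tavg, rh, wind, dtr, precip).
#' @param pollutant_mean Stationary mean of the pollutant series (ug/m3).
#' @param pollutant_seasonal_amplitude Amplitude of its annual cycle (ug/m3).
#' @param pollutant_ar Autoregressive coefficient of the daily deviations,
#'   in [0, 1).
#' @param pollutant_sd Innovation standard deviation (ug/m3).
#' @param phi Overdispersion of the counts (>= 1; 1 = Poisson).
#' @param surface A [true_surface()] ground truth.
#' @param seed Integer RNG seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_cities = 3L,
                       start_date = "2016-01-01", end_date = "2019-12-31",
                       baseline_log_rate = log(20),
                       seasonal_amplitude = c(0.15, 0.05),
                       gamma = c(tavg = 0.006, rh = 0, wind = 0, dtr = 0, precip = 0),
                       pollutant_mean = 45,
                       pollutant_seasonal_amplitude = 12,
                       pollutant_ar = 0.7,
                       pollutant_sd = 8,
                       phi = 1.5,
                       surface = true_surface(),
                       seed = 1L) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  n_days <- as.integer(end_date - start_date) + 1L
  if (n_days < surface$max_lag + 1L) {
    stop("sim_config: date range must cover at least max_lag + 1 days", call. = FALSE)
  }
  if (phi < 1) stop("sim_config: `phi` must be >= 1", call. = FALSE)
  if (pollutant_ar < 0 || pollutant_ar >= 1) {
    stop("sim_config: `pollutant_ar` must lie in [0, 1)", call. = FALSE)
  }
  met_names <- c("tavg", "rh", "wind", "dtr", "precip")
  if (is.null(names(gamma))) names(gamma) <- met_names[seq_along(gamma)]
  g <- stats::setNames(numeric(5), met_names)
  g[names(gamma)] <- gamma
  structure(
    list(
      n_cities = as.integer(n_cities),
      start_date = start_date, end_date = end_date, n_days = n_days,
      baseline_log_rate = rep_len(baseline_log_rate, n_cities),
      seasonal_amplitude = seasonal_amplitude,
      gamma = g,
      pollutant_mean = pollutant_mean,
      pollutant_seasonal_amplitude = pollutant_seasonal_amplitude,
      pollutant_ar = pollutant_ar,
      pollutant_sd = pollutant_sd,
      phi = phi,
      surface = surface,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @keywords internal
simulate_city <- function(config, city_idx) {
  n <- config$n_days
  t <- 0:(n - 1L)
  dates <- seq(config$start_date, by = "day", length.out = n)
  doy <- t %% 365

  # meteorology: independent seasonal sinusoids plus noise
  tavg <- 13 + 11 * sin(2 * pi * (doy - 105) / 365) + stats::rnorm(n, 0, 3)
  half_range <- pmax(0.5, stats::rnorm(n, 4, 1.2))
  tmax <- tavg + half_range
  tmin <- tavg - half_range
  dtr <- tmax - tmin
  rh <- pmin(100, pmax(5, 68 + 10 * sin(2 * pi * (doy - 160) / 365) + stats::rnorm(n, 0, 8)))
  wind <- pmax(0.1, 2.3 + 0.4 * sin(2 * pi * (doy - 30) / 365) + stats::rnorm(n, 0, 0.8))
  precip <- ifelse(stats::runif(n) < 0.3, stats::rgamma(n, shape = 0.7, scale = 12), 0)

  # pollutant: winter-peaking seasonal mean plus AR(1) deviations, positive
  seas <- config$pollutant_seasonal_amplitude * cos(2 * pi * (doy - 15) / 365)
  e <- numeric(n)
  innov <- stats::rnorm(n, 0, config$pollutant_sd)
  e[1] <- innov[1] / sqrt(1 - config$pollutant_ar^2)
  for (i in 2:n) e[i] <- config$pollutant_ar * e[i - 1L] + innov[i]
  x <- pmax(1, config$pollutant_mean + seas + e)

  # exposure history before day 0 padded with the stationary mean
  L <- config$surface$max_lag
  xpad <- c(rep(config$pollutant_mean, L), x)
  lag_effect <- numeric(n)
  if (config$surface$family != "null") {
    for (l in 0:L) {
      xl <- xpad[(L + 1L):(L + n) - l]
      lag_effect <- lag_effect + config$surface$eval(xl, rep(l, n))
    }
  }

  M <- cbind(tavg = tavg, rh = rh, wind = wind, dtr = dtr, precip = precip)
  seasonal <- numeric(n)
  for (k in seq_along(config$seasonal_amplitude)) {
    seasonal <- seasonal + config$seasonal_amplitude[k] * cos(2 * pi * k * (t - 20) / 365)
  }
  eta <- config$baseline_log_rate[city_idx] + lag_effect +
    drop(M %*% config$gamma) + seasonal
  mu <- exp(eta)
  if (config$phi == 1) {
    y <- stats::rpois(n, mu)
  } else {
    # NB2 with size = mu / (phi - 1) gives Var = phi * mu
    y <- stats::rnbinom(n, size = mu / (config$phi - 1), mu = mu)
  }
  data.frame(
    city = sprintf("city%02d", city_idx),
    date = dates,
    y = y,
    x = x,
    tavg = tavg, rh = rh, wind = wind, dtr = dtr, precip = precip,
    tmax = tmax, tmin = tmin,
    mu = mu,
    stringsAsFactors = FALSE
  )
}

#' Simulate a multi-city daily panel with known ground truth
#'
#' One row per (city, day): overdispersed admission counts whose log mean is
#' baseline + true exposure-lag effect + linear meteorology effects + annual
#' seasonality; a positive seasonal AR(1) pollutant series; and five
#' independent meteorological covariates (DTR computed as simulated daily
#' maximum minus minimum temperature). Exposure history before the panel
#' start is padded with the pollutant stationary mean so every day carries a
#' full lag window. Output is bit-identical for identical configs and seeds.
#'
#' @param config A [sim_config()].
#' @return List with `panel` (data frame; columns city, date, y, x, tavg,
#'   rh, wind, dtr, precip, plus generator-side tmax, tmin, mu) and
#'   `surface` (the ground truth).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  panels <- lapply(seq_len(config$n_cities), function(j) simulate_city(config, j))
  list(panel = do.call(rbind, panels), surface = config$surface)
}

#' Write a simulated panel to the three-table CSV layout
#'
#' Emits `admissions.csv` (date, city, disease, count), `airquality.csv`
#' (date, city, pollutant, value) and `meteorology.csv` (date, city, tavg,
#' rh, wind, dtr, precip), plus a `truth.json` sidecar recording the
#' simulation parameters and surface.
#'
#' @param sim Result of [simulate_panel()].
#' @param config The [sim_config()] used.
#' @param dir Output directory (created if needed).
#' @param disease,pollutant Labels written into the tables.
#' @return Invisibly, the paths of the four files.
#' @export
write_panel_tables <- function(sim, config, dir,
                               disease = "resp", pollutant = "pm10") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- sim$panel
  adm <- data.frame(date = format(p$date), city = p$city,
                    disease = disease, count = p$y)
  air <- data.frame(date = format(p$date), city = p$city,
                    pollutant = pollutant, value = p$x)
  met <- data.frame(date = format(p$date), city = p$city,
                    tavg = p$tavg, rh = p$rh, wind = p$wind,
                    dtr = p$dtr, precip = p$precip)
  paths <- file.path(dir, c("admissions.csv", "airquality.csv",
                            "meteorology.csv", "truth.json"))
  utils::write.csv(adm, paths[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(air, paths[2], row.names = FALSE, quote = FALSE)
  utils::write.csv(met, paths[3], row.names = FALSE, quote = FALSE)
  truth <- list(
    surface = c(list(family = config$surface$family,
                     max_lag = config$surface$max_lag,
                     x_ref = config$surface$x_ref),
                config$surface$params),
    config = list(
      n_cities = config$n_cities,
      start_date = format(config$start_date),
      end_date = format(config$end_date),
      baseline_log_rate = config$baseline_log_rate,
      seasonal_amplitude = config$seasonal_amplitude,
      gamma = as.list(config$gamma),
      pollutant_mean = config$pollutant_mean,
      pollutant_seasonal_amplitude = config$pollutant_seasonal_amplitude,
      pollutant_ar = config$pollutant_ar,
      pollutant_sd = config$pollutant_sd,
      phi = config$phi,
      seed = config$seed
    )
  )
  jsonlite::write_json(truth, paths[4], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
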
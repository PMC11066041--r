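# small fitted model reused across blocks
make_fit <- function(seed = 81, years = 3, max_lag = 14, df_p = 4, df_l = 4) {
  cfg <- sim_config(n_cities = 1, start_date = "2016-01-01",
                    end_date = sprintf("%d-12-31", 2015 + years), seed = seed)
  sim <- simulate_panel(cfg)
  p <- sim$panel
  f <- fit_city(p, "tavg", max_lag, df_p, df_l)
  list(fit = f$fit, cb = f$cb, panel = p, surface = sim$surface)
}

test_that("the reference identity holds exactly and null coefficients give RR = 1", {
  m <- make_fit()
  xr <- median(m$panel$x)
  ov <- overall_cumulative(m$fit, m$cb, x_ref = xr)
  at_ref <- overall_cumulative(m$fit, m$cb, at = xr, x_ref = xr)
  expect_identical(at_ref$log_rr, 0)
  expect_identical(at_ref$se, 0)
  expect_identical(at_ref$rr, 1)

  sf <- exposure_lag_surface(m$fit, m$cb, at = xr, x_ref = xr)
  expect_equal(sf$rr, rep(1, nrow(sf)))

  # zero coefficient block: flat curve at RR = 1 with symmetric CI
  d <- ncol(m$cb$matrix)
  null_est <- list(beta = rep(0, d), vcov = diag(1e-4, d))
  ov0 <- overall_cumulative(null_est, m$cb, x_ref = xr)
  expect_equal(ov0$rr, rep(1, 100))
  ex0 <- extreme_effects(null_est, m$cb, m$panel$x)
  expect_equal(ex0$rr, rep(1, nrow(ex0)))
  expect_equal(ex0$rr * ex0$rr, ex0$rr_low * ex0$rr_high, tolerance = 1e-12)

  # CI ordering and non-negative se everywhere
  expect_true(all(ov$se >= 0))
  expect_true(all(ov$rr_low <= ov$rr & ov$rr <= ov$rr_high))
})

test_that("summing the surface over integer lags reproduces the cumulative curve", {
  m <- make_fit(seed = 82, max_lag = 3, df_p = 2, df_l = 2)
  xr <- median(m$panel$x)
  at <- seq(15, 75, length.out = 20)
  ov <- overall_cumulative(m$fit, m$cb, at = at, x_ref = xr)
  sf <- exposure_lag_surface(m$fit, m$cb, at = at, lags = 0:3, x_ref = xr)
  summed <- tapply(sf$log_rr, sf$x, sum)
  expect_lt(max(abs(summed[as.character(at)] - ov$log_rr)), 1e-10)
})

test_that("dimension mismatches between estimate and cross-basis are caught", {
  m <- make_fit(seed = 83, max_lag = 3, df_p = 2, df_l = 2)
  bad <- list(beta = rep(0, 9), vcov = diag(9))
  expect_error(overall_cumulative(bad, m$cb, x_ref = 40), "coefficients")
})

test_that("extreme contrasts honour self-contrast, degeneracy and the lag decay", {
  m <- make_fit()
  ex_self <- extreme_effects(m$fit, m$cb, m$panel$x, levels = c(0.5, 0.5, 0.5))
  expect_equal(ex_self$rr, rep(1, nrow(ex_self)))
  expect_error(extreme_effects(m$fit, m$cb, rep(40, 100)), "degenerate")
  expect_error(extreme_effects(m$fit, m$cb, numeric(0)), "empty")

  # the generator's geometric lag weights imply |log RR| decaying in lag,
  # within CI half-widths
  for (s in 1:3) {
    ms <- make_fit(seed = s)
    ex <- extreme_effects(ms$fit, ms$cb, ms$panel$x)
    hi <- ex[ex$contrast == "high_vs_median", ]
    slack <- 1.96 * (hi$se[-1] + hi$se[-nrow(hi)])
    expect_true(all(diff(abs(hi$log_rr)) <= slack))
  }
  # quantile values are carried for reporting
  q <- attr(extreme_effects(m$fit, m$cb, m$panel$x), "quantiles")
  expect_equal(unname(q), unname(quantile(m$panel$x, c(.1, .5, .9))), tolerance = 1e-12)
})

test_that("surface estimation error shrinks with a longer panel", {
  err <- function(years, seed) {
    m <- make_fit(seed = seed, years = years)
    xr <- median(m$panel$x)
    at <- seq(quantile(m$panel$x, .02), quantile(m$panel$x, .98), length.out = 40)
    sf <- exposure_lag_surface(m$fit, m$cb, at = at, x_ref = xr)
    tr <- surface_eval(m$surface, sf$x, sf$lag) -
      surface_eval(m$surface, rep(xr, nrow(sf)), sf$lag)
    mean(abs(sf$log_rr - tr))
  }
  e_short <- mean(vapply(1:5, function(s) err(3, s), numeric(1)))
  e_long <- mean(vapply(1:5, function(s) err(10, s), numeric(1)))
  expect_lt(e_long, e_short)
})
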
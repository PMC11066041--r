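test_that("null-effect configuration yields Poisson counts at the baseline rate", {
  cfg <- sim_config(n_cities = 1, start_date = "2016-01-01", end_date = "2029-09-09",
                    baseline_log_rate = log(10), seasonal_amplitude = 0,
                    gamma = c(tavg = 0), phi = 1, surface = true_surface("null"),
                    seed = 101)
  p <- simulate_panel(cfg)$panel
  expect_equal(nrow(p), 5001L)
  # sample mean tracks exp(alpha) = 10 (sd of the mean ~ 0.045)
  expect_lt(abs(mean(p$y) - 10), 0.3)
  # Pearson dispersion against the intercept-only mean concentrates near 1
  mu <- mean(p$y)
  disp <- sum((p$y - mu)^2 / mu) / (length(p$y) - 1)
  expect_gt(disp, 0.9)
  expect_lt(disp, 1.1)
})

test_that("overdispersed counts honour the Var = phi * mu contract", {
  cfg <- sim_config(n_cities = 1, start_date = "2016-01-01", end_date = "2029-09-09",
                    baseline_log_rate = log(10), seasonal_amplitude = 0,
                    gamma = c(tavg = 0), phi = 1.5, surface = true_surface("null"),
                    seed = 103)
  p <- simulate_panel(cfg)$panel
  mu <- mean(p$y)
  disp <- sum((p$y - mu)^2 / mu) / (length(p$y) - 1)
  expect_gt(disp, 1.3)
  expect_lt(disp, 1.7)
})

test_that("DTR is max minus min temperature and panel geometry is conserved", {
  cfg <- sim_config(n_cities = 3, seed = 107)
  p <- simulate_panel(cfg)$panel
  expect_equal(p$dtr, p$tmax - p$tmin, tolerance = 1e-12)
  expect_true(all(p$dtr >= 0))
  expect_true(all(p$rh >= 0 & p$rh <= 100))
  expect_true(all(p$precip >= 0))
  expect_true(all(p$x > 0))
  # one row per (city, day), consecutive dates, no gaps
  expect_equal(nrow(p), 3L * cfg$n_days)
  for (ct in unique(p$city)) {
    d <- p$date[p$city == ct]
    expect_equal(as.integer(diff(d)), rep(1L, length(d) - 1L))
  }
})

test_that("simulation is seed-deterministic and seeds differ", {
  cfg <- sim_config(seed = 109)
  a <- simulate_panel(cfg)$panel
  b <- simulate_panel(cfg)$panel
  expect_identical(a, b)
  c <- simulate_panel(sim_config(seed = 110))$panel
  expect_false(isTRUE(all.equal(a$x, c$x)))
})

test_that("empirical count means track the generator means", {
  cfg <- sim_config(seed = 113)
  p <- simulate_panel(cfg)$panel
  expect_lt(abs(mean(p$y / p$mu) - 1), 0.02)
  # stratified by rounded mean: observed group means follow mu
  grp <- round(p$mu / 5) * 5
  tab <- tapply(p$y, grp, mean)
  mu_tab <- tapply(p$mu, grp, mean)
  big <- names(tab)[table(grp)[names(tab)] > 100]
  expect_lt(max(abs(tab[big] / mu_tab[big] - 1)), 0.1)
})

test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(start_date = "2016-01-01", end_date = "2016-01-05"),
               "max_lag")
  expect_error(sim_config(phi = 0.5), "phi")
  expect_error(sim_config(pollutant_ar = 1), "pollutant_ar")
  expect_error(true_surface(decay = 1.2))
})

test_that("the ground-truth surface is zero at its reference for every lag", {
  s <- true_surface()
  expect_equal(surface_eval(s, rep(s$x_ref, 15), 0:14), rep(0, 15))
  expect_equal(surface_cumulative(s, s$x_ref), 0)
  # cumulative equals the closed-form quadratic contrast g(x) - g(x_ref)
  g <- function(x) s$params$amplitude * (1 - ((x - s$params$peak) / s$params$width)^2)
  xs <- c(10, 30, 60, 80)
  expect_equal(surface_cumulative(s, xs), g(xs) - g(s$x_ref), tolerance = 1e-12)
})
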
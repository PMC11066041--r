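test_that("candidate enumeration counts and order follow the binary-counter scheme", {
  # no covariates, singleton grid: exactly one exposure-only shell
  g0 <- search_grid(max_lags = 7, df_p_values = 2, df_l_values = 2,
                    covariates = character(0))
  e0 <- enumerate_candidates(g0)
  expect_equal(nrow(e0), 1L)
  expect_equal(e0$covariates, "")

  # two covariates: masks {}, {a}, {b}, {a,b} in counter order
  g2 <- search_grid(max_lags = 7, df_p_values = 2, df_l_values = 2,
                    covariates = c("a", "b"))
  e2 <- enumerate_candidates(g2)
  expect_equal(nrow(e2), 4L)
  expect_equal(e2$covariates, c("", "a", "b", "a,b"))

  # default grid: 2^5 masks x 25 lags x 4 df_p x 4 df_l
  ed <- enumerate_candidates(search_grid())
  expect_equal(nrow(ed), 2^5 * 25 * 4 * 4)
  # hyperparameters cycle lexicographically within each mask
  expect_equal(ed$max_lag[1:3], c(7L, 7L, 7L))
  expect_equal(ed$df_l[1:5], c(2L, 3L, 4L, 5L, 2L))
  expect_error(search_grid(max_lags = integer(0)), "non-empty")
})

test_that("the delta-QAIC < 2 parsimony rule selects as stated", {
  cand <- function(qaics, ncov) {
    data.frame(id = seq_along(qaics), qaic = qaics, n_covariates = ncov,
               df_p = 2L, df_l = 2L, max_lag = 7L)
  }
  # simple model within 2 of the optimum wins
  c1 <- cand(c(100.0, 101.5), c(3L, 1L))
  expect_equal(select_best(c1)$id, 2L)
  # simple model at delta = 2.1 loses
  c2 <- cand(c(100.0, 102.1), c(3L, 1L))
  expect_equal(select_best(c2)$id, 1L)
  # coincident optimum and simplest
  c3 <- cand(c(100.0, 101.9), c(1L, 3L))
  expect_equal(select_best(c3)$id, 1L)
  expect_error(select_best(cand(NA_real_, 1L)), "finite")
})

test_that("optimization fits all candidates on one common window and is reproducible", {
  cfg <- sim_config(n_cities = 1, start_date = "2016-01-01",
                    end_date = "2017-12-31", seed = 71)
  p <- simulate_panel(cfg)$panel
  g <- search_grid(max_lags = c(7, 14), df_p_values = 2:3, df_l_values = 2,
                   covariates = c("tavg", "rh"))
  opt <- optimize_dlnm(p, g)
  expect_equal(nrow(opt$table), 4 * 2 * 2 * 1)
  expect_true(all(is.finite(opt$table$qaic)))
  # common window: refit length is n minus the largest lag in the grid
  expect_equal(opt$refit$fit$n, nrow(p) - 14L)
  # deterministic: rerunning gives the identical QAIC table and selection
  opt2 <- optimize_dlnm(p, g)
  expect_identical(opt$table, opt2$table)
  expect_identical(opt$selected, opt2$selected)

  # singleton grid returns that shell
  g1 <- search_grid(max_lags = 7, df_p_values = 2, df_l_values = 2,
                    covariates = character(0))
  opt1 <- optimize_dlnm(p, g1)
  expect_equal(nrow(opt1$table), 1L)
  expect_equal(opt1$selected$id, 1L)
})

test_that("a strongly temperature-driven panel selects temperature almost always", {
  g <- search_grid(max_lags = 14, df_p_values = 3, df_l_values = 3)
  hits <- vapply(1:10, function(s) {
    cfg <- sim_config(n_cities = 1, start_date = "2016-01-01",
                      end_date = "2018-12-31", gamma = c(tavg = 0.02), seed = s)
    p <- simulate_panel(cfg)$panel
    grepl("tavg", optimize_dlnm(p, g)$selected$covariates)
  }, logical(1))
  expect_gte(sum(hits), 9L)
})
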
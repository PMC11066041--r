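test_that("a minimal three-table join produces one fully populated row", {
  dir <- withr::local_tempdir()
  set.seed(61)
  paths <- write_toy_tables(dir, "2016-01-01", counts = 5, values = 38.2)
  p <- read_panel(paths[1], paths[2], paths[3], "Seoul", "asthma", "pm10")
  expect_equal(nrow(p), 1L)
  expect_equal(p$y, 5L)
  expect_equal(p$x, 38.2)
  expect_false(anyNA(p))
})

test_that("schema and integrity violations raise their designated errors", {
  dir <- withr::local_tempdir()
  set.seed(62)
  dates <- format(seq(as.Date("2016-01-01"), by = "day", length.out = 5))
  paths <- write_toy_tables(dir, dates, counts = 1:5, values = runif(5, 20, 60))

  # missing required column named in the error
  adm <- read.csv(paths[1])
  write.csv(adm[, setdiff(names(adm), "count")], paths[1], row.names = FALSE)
  expect_error(read_panel(paths[1], paths[2], paths[3], "Seoul", "asthma", "pm10"),
               "count")

  # gap in the date sequence lists the missing date
  paths <- write_toy_tables(dir, dates[c(1, 3, 4, 5)], counts = 1:4,
                            values = runif(4, 20, 60))
  expect_error(read_panel(paths[1], paths[2], paths[3], "Seoul", "asthma", "pm10"),
               "2016-01-02")

  # duplicate (date, city) key
  paths <- write_toy_tables(dir, dates[c(1, 2, 2, 3, 4)], counts = 1:5,
                            values = runif(5, 20, 60))
  expect_error(read_panel(paths[1], paths[2], paths[3], "Seoul", "asthma", "pm10"),
               "duplicate")

  # negative count
  paths <- write_toy_tables(dir, dates, counts = c(1, -2, 3, 4, 5),
                            values = runif(5, 20, 60))
  expect_error(read_panel(paths[1], paths[2], paths[3], "Seoul", "asthma", "pm10"),
               "non-negative")
})

test_that("simulated panels survive a write/read round trip and row shuffling", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_cities = 2, start_date = "2016-01-01",
                    end_date = "2016-03-31", seed = 63)
  sim <- simulate_panel(cfg)
  write_panel_tables(sim, cfg, dir)
  p <- read_panel(file.path(dir, "admissions.csv"), file.path(dir, "airquality.csv"),
                  file.path(dir, "meteorology.csv"), "city01", "resp", "pm10")
  orig <- sim$panel[sim$panel$city == "city01", ]
  expect_equal(p$y, orig$y)
  expect_equal(p$x, orig$x, tolerance = 1e-9)
  expect_equal(p$tavg, orig$tavg, tolerance = 1e-9)
  expect_equal(p$date, orig$date)

  # shuffling the input rows yields the same panel
  for (f in c("admissions.csv", "airquality.csv", "meteorology.csv")) {
    tab <- read.csv(file.path(dir, f))
    set.seed(64)
    write.csv(tab[sample(nrow(tab)), ], file.path(dir, f), row.names = FALSE)
  }
  p2 <- read_panel(file.path(dir, "admissions.csv"), file.path(dir, "airquality.csv"),
                   file.path(dir, "meteorology.csv"), "city01", "resp", "pm10")
  expect_equal(p2, p, tolerance = 1e-9)

  # the truth sidecar records the surface and config
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$surface$max_lag, cfg$surface$max_lag)
  expect_equal(truth$config$seed, 63L)
})

test_that("period split partitions the panel at the pandemic boundary", {
  cfg <- sim_config(n_cities = 1, start_date = "2016-01-01",
                    end_date = "2020-12-31", seed = 65)
  p <- simulate_panel(cfg)$panel
  sp <- split_periods(p, period_split())
  expect_equal(range(sp$pre$date), as.Date(c("2016-01-01", "2019-12-31")))
  expect_equal(range(sp$post$date), as.Date(c("2020-01-01", "2020-12-31")))
  expect_equal(nrow(sp$pre) + nrow(sp$post), nrow(p))
  expect_length(intersect(format(sp$pre$date), format(sp$post$date)), 0)

  # re-splitting the pre panel: pre part unchanged, post part empty -> error
  expect_error(split_periods(sp$pre, period_split()), "post")
  expect_error(period_split(pre_end = "2020-06-30"), "disjoint")
})
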
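# Shared settings for the analysis scripts. Source()d by each numbered step.

library(lagriskr)

cities <- c("city01", "city02", "city03") # first = reference city
disease <- "resp"
pollutant <- "pm10"
periods <- c("pre", "post")

data_dir <- "results/data"
out_dir <- "results"

# simulation: 3 cities over 2016-2020 so both study periods are populated
analysis_sim_config <- function() {
  sim_config(n_cities = length(cities),
             start_date = "2016-01-01", end_date = "2020-12-31",
             seed = 20160101)
}

# desk-scale search grid: the published grid spans lags 7..31 and df 2..5;
# here a thinned lag set and df 2..4 keep the 2^5-mask search quick while
# still exercising selection in both dimensions
analysis_grid <- function() {
  search_grid(max_lags = c(7, 14, 21, 28), df_p_values = 2:4,
              df_l_values = 2:4)
}

read_city_panel <- function(city) {
  read_panel(file.path(data_dir, "admissions.csv"),
             file.path(data_dir, "airquality.csv"),
             file.path(data_dir, "meteorology.csv"),
             city, disease, pollutant)
}

read_period_panels <- function(period) {
  lapply(setNames(cities, cities), function(ct) {
    split_periods(read_city_panel(ct), period_split())[[period]]
  })
}
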
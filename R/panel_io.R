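#' Read and merge the three input tables into one analysis panel
#'
#' Inner-joins daily admission counts, pollutant concentrations and
#' meteorology on (date, city) for one disease, one pollutant and one city,
#' validating the schema and the calendar along the way. Returns one row per
#' day, sorted by date.
#'
#' Input layout (CSV, UTF-8, header row, ISO-8601 dates):
#' admissions `date,city,disease,count`; airquality
#' `date,city,pollutant,value`; meteorology
#' `date,city,tavg,rh,wind,dtr,precip`.
#'
#' @param admissions_path,airquality_path,meteorology_path CSV file paths.
#' @param city City identifier to select.
#' @param disease Disease label to select from the admissions table.
#' @param pollutant Pollutant label to select from the air-quality table.
#' @param interpolate_gaps If `TRUE`, pollutant/meteorology gaps of at most
#'   two consecutive days are filled by linear interpolation instead of
#'   failing. Count gaps always fail.
#' @return A data frame (`daily_panel`) with columns city, date, y, x, tavg,
#'   rh, wind, dtr, precip.
#' @export
read_panel <- function(admissions_path, airquality_path, meteorology_path,
                       city, disease, pollutant, interpolate_gaps = FALSE) {
  adm <- read_checked(admissions_path, c("date", "city", "disease", "count"))
  air <- read_checked(airquality_path, c("date", "city", "pollutant", "value"))
  met <- read_checked(meteorology_path,
                      c("date", "city", "tavg", "rh", "wind", "dtr", "precip"))

  adm <- adm[adm$city == city & adm$disease == disease, c("date", "count")]
  air <- air[air$city == city & air$pollutant == pollutant, c("date", "value")]
  met <- met[met$city == city,
             c("date", "tavg", "rh", "wind", "dtr", "precip")]
  if (nrow(adm) == 0L) stop(sprintf(
    "read_panel: no admissions rows for city '%s', disease '%s'", city, disease
  ), call. = FALSE)

  for (nm in c("adm", "air", "met")) {
    tab <- get(nm)
    if (anyDuplicated(tab$date)) {
      dup <- tab$date[duplicated(tab$date)][1]
      stop(sprintf(
        "read_panel: duplicate (date, city) key in %s table: %s / %s",
        nm, format(dup), city
      ), call. = FALSE)
    }
  }
  check_date_gaps(adm$date, "admissions")
  if (interpolate_gaps) {
    air <- fill_small_gaps(air, "value")
    met <- fill_small_gaps(met, c("tavg", "rh", "wind", "dtr", "precip"))
  }
  check_date_gaps(air$date, "airquality")
  check_date_gaps(met$date, "meteorology")

  panel <- merge(merge(adm, air, by = "date"), met, by = "date")
  panel <- panel[order(panel$date), ]
  check_date_gaps(panel$date, "merged panel")
  out <- data.frame(
    city = city,
    date = panel$date,
    y = panel$count,
    x = panel$value,
    tavg = panel$tavg, rh = panel$rh, wind = panel$wind,
    dtr = panel$dtr, precip = panel$precip,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  validate_panel(out)
  out
}

#' @keywords internal
read_checked <- function(path, required) {
  if (!file.exists(path)) {
    stop(sprintf("read_panel: file not found: %s", path), call. = FALSE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop(sprintf(
      "read_panel: %s is missing required column(s): %s",
      basename(path), paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  tab$date <- as.Date(tab$date)
  if (anyNA(tab$date)) {
    stop(sprintf("read_panel: unparseable date(s) in %s", basename(path)),
         call. = FALSE)
  }
  tab
}

#' @keywords internal
check_date_gaps <- function(dates, label) {
  dates <- sort(dates)
  full <- seq(min(dates), max(dates), by = "day")
  missing <- setdiff(format(full), format(dates))
  if (length(missing)) {
    stop(sprintf(
      "read_panel: %s has gap(s) in the date sequence; missing: %s",
      label, paste(utils::head(missing, 10), collapse = ", ")
    ), call. = FALSE)
  }
  invisible(TRUE)
}

#' @keywords internal
fill_small_gaps <- function(tab, value_cols, max_gap = 2L) {
  dates <- sort(tab$date)
  full <- seq(min(dates), max(dates), by = "day")
  missing <- as.Date(setdiff(format(full), format(dates)))
  if (length(missing) == 0L) return(tab)
  runs <- split(missing, cumsum(c(1, diff(missing) != 1)))
  if (any(lengths(runs) > max_gap)) {
    stop(sprintf(
      "read_panel: gap longer than %d days cannot be interpolated", max_gap
    ), call. = FALSE)
  }
  add <- data.frame(date = missing)
  for (v in value_cols) {
    add[[v]] <- stats::approx(as.numeric(tab$date), tab[[v]],
                              xout = as.numeric(missing))$y
  }
  extra <- setdiff(names(tab), c("date", value_cols))
  for (v in extra) add[[v]] <- tab[[v]][1]
  out <- rbind(tab, add[, names(tab)])
  out[order(out$date), ]
}

#' @keywords internal
validate_panel <- function(panel) {
  if (any(panel$y < 0) || any(panel$y != round(panel$y))) {
    stop("read_panel: admission counts must be non-negative integers",
         call. = FALSE)
  }
  if (any(panel$x < 0)) {
    stop("read_panel: pollutant concentration must be >= 0", call. = FALSE)
  }
  if (any(panel$rh < 0 | panel$rh > 100)) {
    stop("read_panel: relative humidity must lie in [0, 100]", call. = FALSE)
  }
  if (any(panel$dtr < 0)) {
    stop("read_panel: diurnal temperature range must be >= 0", call. = FALSE)
  }
  if (any(panel$precip < 0)) {
    stop("read_panel: precipitation must be >= 0", call. = FALSE)
  }
  invisible(panel)
}

#' Period split definition
#'
#' @param pre_start,pre_end,post_start,post_end Calendar dates. Defaults are
#'   the pre-pandemic years 2016-2019 and the first pandemic year 2020.
#' @return An object of class `period_split`.
#' @export
period_split <- function(pre_start = "2016-01-01", pre_end = "2019-12-31",
                         post_start = "2020-01-01", post_end = "2020-12-31") {
  pre <- as.Date(c(pre_start, pre_end))
  post <- as.Date(c(post_start, post_end))
  stopifnot(pre[1] <= pre[2], post[1] <= post[2])
  if (pre[2] >= post[1]) {
    stop("period_split: intervals must be disjoint with pre before post",
         call. = FALSE)
  }
  structure(list(pre = pre, post = post), class = "period_split")
}

#' Split a panel into pre and post periods
#'
#' @param panel A daily panel data frame with a `date` column.
#' @param split A [period_split()].
#' @return Named list of two disjoint panels, `pre` and `post`.
#' @export
split_periods <- function(panel, split = period_split()) {
  stopifnot(inherits(split, "period_split"))
  pre <- panel[panel$date >= split$pre[1] & panel$date <= split$pre[2], ]
  post <- panel[panel$date >= split$post[1] & panel$date <= split$post[2], ]
  if (nrow(pre) == 0L) {
    stop("split_periods: panel has no rows in the pre period", call. = FALSE)
  }
  if (nrow(post) == 0L) {
    stop("split_periods: panel has no rows in the post period", call. = FALSE)
  }
  rownames(pre) <- rownames(post) <- NULL
  list(pre = pre, post = post)
}
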
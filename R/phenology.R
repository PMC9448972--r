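#' Egg-to-larva development time from first-observation dates
#'
#' Whole-day difference between the date the first egg and the first
#' last-instar larva were observed in a year. First observations are taken
#' jointly across patches (the minimum date over patch records) when
#' vectors of dates are supplied.
#'
#' @param first_egg_date,first_l5_date Dates (or ISO-8601 strings); vectors
#'   are reduced to their earliest date.
#' @return Development time in whole days (> 0).
#' @examples
#' development_time("1993-06-07", "1993-07-14")  # 37
#' @export
development_time <- function(first_egg_date, first_l5_date) {
  d1 <- min(as.Date(first_egg_date))
  d2 <- min(as.Date(first_l5_date))
  if (anyNA(c(d1, d2))) stop("invalid date(s)")
  if (format(d1, "%Y") != format(d2, "%Y")) {
    stop("first egg and first larva dates must fall in the same year")
  }
  dt <- as.numeric(d2 - d1)
  if (dt <= 0) {
    stop("first larva date must be after first egg date ",
         "(development time must be positive)")
  }
  dt
}

#' Mean temperature over an observed development window
#'
#' Arithmetic mean of daily temperatures over the closed date interval
#' `[start_date, end_date]` (both endpoint days included). The series must
#' cover every day of the window; gaps are an error listing the missing
#' dates.
#'
#' @param daily_temps data.frame with columns `date` (Date or ISO-8601) and
#'   `temp` (deg C).
#' @param start_date,end_date window endpoints.
#' @return Mean temperature in deg C.
#' @export
window_mean_temperature <- function(daily_temps, start_date, end_date) {
  daily_temps <- as.data.frame(daily_temps)
  if (!all(c("date", "temp") %in% names(daily_temps))) {
    stop("daily_temps needs columns 'date' and 'temp'")
  }
  dates <- as.Date(daily_temps$date)
  start <- as.Date(start_date)
  end <- as.Date(end_date)
  if (end < start) stop("end_date before start_date")
  wanted <- seq(start, end, by = "day")
  idx <- match(wanted, dates)
  if (anyNA(idx)) {
    stop("daily temperature series has gaps in the window: missing ",
         paste(format(wanted[is.na(idx)]), collapse = ", "))
  }
  mean(daily_temps$temp[idx])
}

#' Development time vs temperature regression
#'
#' Ordinary least-squares regression of the annual egg-to-larva development
#' time (days) on the mean temperature over the observed development
#' window. Summarises how much a warmer summer shortens the window of
#' vulnerability; slopes are in days per deg C.
#'
#' @param records data.frame with columns `dev_time_days` and
#'   `window_mean_temp` (one row per year; other columns ignored). At least
#'   3 complete rows required.
#' @param conf confidence level for the slope interval (default 0.95,
#'   symmetric t-based).
#' @return A list with `slope` (days/deg C), `intercept`, `conf_int`
#'   (length-2 vector), `r_squared`, `n`, and the underlying `lm` fit.
#' @export
devtime_temperature_regression <- function(records, conf = 0.95) {
  records <- as.data.frame(records)
  if (!all(c("dev_time_days", "window_mean_temp") %in% names(records))) {
    stop("records needs columns 'dev_time_days' and 'window_mean_temp'")
  }
  ok <- stats::complete.cases(records[c("dev_time_days",
                                        "window_mean_temp")])
  records <- records[ok, ]
  if (nrow(records) < 3) stop("need at least 3 complete records")
  if (stats::sd(records$window_mean_temp) == 0) {
    stop("temperature has zero variance; slope undefined")
  }
  m <- stats::lm(dev_time_days ~ window_mean_temp, data = records)
  ci <- stats::confint(m, "window_mean_temp", level = conf)
  list(slope = unname(stats::coef(m)[["window_mean_temp"]]),
       intercept = unname(stats::coef(m)[["(Intercept)"]]),
       conf_int = as.numeric(ci),
       r_squared = summary(m)$r.squared,
       n = nrow(records),
       fit = m)
}
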
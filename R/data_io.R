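#' Annual census dataset for the two-stage population model
#'
#' A `moth_data` object bundles the annual pooled census counts (eggs laid
#' \eqn{E_t}, eggs hatched, fifth-instar larvae \eqn{L_t}), phenology dates,
#' egg-to-larva development times \eqn{d_t}, and (optionally) the per-year
#' weather covariates used by the model variants.
#'
#' @param observations data.frame with one row per year. Required columns:
#'   `year`, `eggs_laid`, `larvae_l5`. Optional: `eggs_hatched`,
#'   `first_egg_date`, `first_l5_date` (Date or ISO-8601 strings),
#'   `dev_time_days`, and the egg-fate tallies `fate_hatched`,
#'   `fate_parasitized`, `fate_predated`, `fate_unhatched_dead`.
#' @param weather optional data.frame as returned by [read_weather()].
#' @param pooled logical; `TRUE` when counts are pooled over habitat patches.
#'
#' @details Development times are derived as `first_l5_date - first_egg_date`
#'   (whole days) for rows where both dates are present and `dev_time_days`
#'   is missing. An explicit `dev_time_days` value takes precedence; a
#'   conflict of more than half a day with the date-derived value raises a
#'   warning. Egg-fate tallies, when present, must sum to `eggs_laid`.
#'
#' @return A validated object of class `moth_data`.
#' @seealso [read_counts()], [read_weather()], [generate_dataset()]
#' @export
moth_data <- function(observations, weather = NULL, pooled = TRUE) {
  obs <- as.data.frame(observations)
  req <- c("year", "eggs_laid", "larvae_l5")
  miss <- setdiff(req, names(obs))
  if (length(miss) > 0) {
    stop("missing required columns: ", paste(miss, collapse = ", "))
  }
  for (col in c("first_egg_date", "first_l5_date")) {
    if (col %in% names(obs) && !inherits(obs[[col]], "Date")) {
      obs[[col]] <- as.Date(as.character(obs[[col]]))
    }
  }
  num_cols <- intersect(
    c("year", "eggs_laid", "eggs_hatched", "larvae_l5", "dev_time_days",
      "fate_hatched", "fate_parasitized", "fate_predated",
      "fate_unhatched_dead"),
    names(obs)
  )
  for (col in num_cols) {
    v <- obs[[col]]
    if (!is.numeric(v)) {
      v2 <- suppressWarnings(as.numeric(as.character(v)))
      if (anyNA(v2) && !all(is.na(v) | is.na(v2) == is.na(v))) {
        stop("non-numeric values in column '", col, "'")
      }
      if (any(!is.na(v) & is.na(v2))) {
        stop("non-numeric values in column '", col, "'")
      }
      obs[[col]] <- v2
    }
  }

  # date-derived development time; explicit column wins
  if (all(c("first_egg_date", "first_l5_date") %in% names(obs))) {
    derived <- as.numeric(obs$first_l5_date - obs$first_egg_date)
    if (!"dev_time_days" %in% names(obs)) {
      obs$dev_time_days <- derived
    } else {
      fill <- is.na(obs$dev_time_days) & !is.na(derived)
      obs$dev_time_days[fill] <- derived[fill]
      both <- !is.na(obs$dev_time_days) & !is.na(derived) & !fill
      conflict <- both & abs(obs$dev_time_days - derived) > 0.5
      if (any(conflict)) {
        warning("dev_time_days differs from date-derived value by > 0.5 day ",
                "in year(s) ", paste(obs$year[conflict], collapse = ", "),
                "; keeping the explicit column")
      }
    }
  }

  x <- structure(
    list(observations = obs,
         weather = if (is.null(weather)) NULL else as.data.frame(weather),
         pooled = isTRUE(pooled)),
    class = "moth_data"
  )
  validate_moth_data(x)
  x
}

#' Validate a `moth_data` object
#'
#' Checks every structural invariant of the data model: counts are
#' non-negative integers with `larvae_l5 <= eggs_laid` and
#' `eggs_hatched <= eggs_laid`; egg-fate tallies (when present) sum to
#' `eggs_laid`; development times are positive; years are strictly
#' increasing with no duplicates; weather years cover observation years.
#' Violations are reported with the offending year.
#'
#' @param x a `moth_data` object.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_moth_data <- function(x) {
  stopifnot(inherits(x, "moth_data"))
  obs <- x$observations
  bad_year <- function(cond, what) {
    if (any(cond, na.rm = TRUE)) {
      yrs <- obs$year[which(cond)]
      stop(what, " in year(s) ", paste(yrs, collapse = ", "))
    }
  }
  if (anyNA(obs$year) || anyNA(obs$eggs_laid) || anyNA(obs$larvae_l5)) {
    stop("year, eggs_laid and larvae_l5 must be complete (no missing values)")
  }
  if (any(obs$year != round(obs$year))) stop("year must be integer-valued")
  if (is.unsorted(obs$year, strictly = TRUE)) {
    stop("years must be strictly increasing with no duplicates")
  }
  count_cols <- intersect(
    c("eggs_laid", "eggs_hatched", "larvae_l5", "fate_hatched",
      "fate_parasitized", "fate_predated", "fate_unhatched_dead"),
    names(obs)
  )
  for (col in count_cols) {
    v <- obs[[col]]
    bad_year(!is.na(v) & (v < 0 | v != round(v)),
             paste0("'", col, "' must be a non-negative integer count"))
  }
  bad_year(obs$larvae_l5 > obs$eggs_laid, "larvae_l5 exceeds eggs_laid")
  if ("eggs_hatched" %in% names(obs)) {
    bad_year(obs$eggs_hatched > obs$eggs_laid, "eggs_hatched exceeds eggs_laid")
  }
  fates <- c("fate_hatched", "fate_parasitized", "fate_predated",
             "fate_unhatched_dead")
  if (all(fates %in% names(obs))) {
    tot <- rowSums(obs[fates])
    bad_year(!is.na(tot) & tot != obs$eggs_laid,
             "egg fate tallies do not sum to eggs_laid")
  }
  if ("dev_time_days" %in% names(obs)) {
    bad_year(!is.na(obs$dev_time_days) & obs$dev_time_days <= 0,
             "dev_time_days must be positive")
  }
  if (!is.null(x$weather)) {
    w <- validate_weather(x$weather)
    missing_yr <- setdiff(obs$year, w$year)
    if (length(missing_yr) > 0) {
      stop("weather table lacks year(s) ", paste(missing_yr, collapse = ", "))
    }
  }
  invisible(x)
}

validate_weather <- function(w) {
  w <- as.data.frame(w)
  if (!"year" %in% names(w)) stop("weather table needs a 'year' column")
  if (anyDuplicated(w$year)) {
    stop("duplicate year(s) in weather table: ",
         paste(unique(w$year[duplicated(w$year)]), collapse = ", "))
  }
  if ("snow_days" %in% names(w)) {
    bad <- !is.na(w$snow_days) & (w$snow_days < 0 | w$snow_days > 365)
    if (any(bad)) {
      stop("snow_days outside [0, 365] in year(s) ",
           paste(w$year[bad], collapse = ", "))
    }
  }
  for (col in intersect(c("summer_mean_temp", "winter_min_temp",
                          "spring_temp"), names(w))) {
    if (any(!is.finite(w[[col]]) & !is.na(w[[col]]))) {
      stop("non-finite values in weather column '", col, "'")
    }
  }
  w
}

#' @export
print.moth_data <- function(x, ...) {
  obs <- x$observations
  cat("Annual insect census dataset (", nrow(obs), " years: ",
      min(obs$year), "-", max(obs$year), ")\n", sep = "")
  cat("  eggs laid   : ", paste(range(obs$eggs_laid), collapse = "-"), "\n",
      sep = "")
  cat("  L5 larvae   : ", paste(range(obs$larvae_l5), collapse = "-"), "\n",
      sep = "")
  if ("dev_time_days" %in% names(obs) && any(!is.na(obs$dev_time_days))) {
    cat("  dev time (d): ",
        paste(round(range(obs$dev_time_days, na.rm = TRUE), 1),
              collapse = "-"), "\n", sep = "")
  }
  cat("  weather     : ", if (is.null(x$weather)) "absent" else "present",
      "; counts ", if (x$pooled) "pooled over patches" else "single patch",
      "\n", sep = "")
  invisible(x)
}

#' Read an annual counts table
#'
#' Reads a comma-separated UTF-8 table (header required, ISO-8601 dates) of
#' annual census counts into a validated [moth_data] object. Development
#' times are derived from the first-egg / first-larva dates where needed.
#'
#' @param path path to a CSV file whose header names the observation fields
#'   (see [moth_data()]).
#' @param weather optional weather data.frame or path to a weather CSV,
#'   attached after validation.
#' @param pooled logical, passed to [moth_data()].
#' @return A `moth_data` object.
#' @export
read_counts <- function(path, weather = NULL, pooled = TRUE) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  obs <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (is.character(weather) && length(weather) == 1) {
    weather <- read_weather(weather)
  }
  moth_data(obs, weather = weather, pooled = pooled)
}

#' Read a per-year weather covariate table
#'
#' Reads and validates the weather covariates feeding the model variants:
#' `summer_mean_temp` (deg C over the development window), `winter_min_temp`
#' (deg C), `snow_days` (days with snow cover, 0-365), `spring_temp`
#' (mean May-June deg C), keyed by `year`.
#'
#' @param path path to a CSV file keyed by year.
#' @return A validated data.frame of weather covariates.
#' @export
read_weather <- function(path) {
  if (!file.exists(path)) stop("weather file not found: ", path)
  w <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  validate_weather(w)
}

#' Write a posterior summary table to CSV
#'
#' Writes the "Estimate (95\% HPD interval)"-style summary produced by
#' [summary.moth_fit()] as a plain CSV with columns `parameter`, `meaning`,
#' `estimate`, `median`, `hpd_lower`, `hpd_upper` (plus any diagnostics
#' columns present, e.g. `rhat`).
#'
#' @param summary a data.frame as returned by [summary.moth_fit()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_summary <- function(summary, path) {
  summary <- as.data.frame(summary)
  utils::write.csv(summary, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a `moth_data` object back to counts (and weather) CSV
#'
#' @param data a `moth_data` object.
#' @param counts_path output path for the observation table.
#' @param weather_path optional output path for the weather table.
#' @return `counts_path`, invisibly.
#' @export
write_counts <- function(data, counts_path, weather_path = NULL) {
  stopifnot(inherits(data, "moth_data"))
  obs <- data$observations
  for (col in c("first_egg_date", "first_l5_date")) {
    if (col %in% names(obs)) obs[[col]] <- format(obs[[col]], "%Y-%m-%d")
  }
  utils::write.csv(obs, counts_path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  if (!is.null(weather_path) && !is.null(data$weather)) {
    utils::write.csv(data$weather, weather_path, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  }
  invisible(counts_path)
}
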
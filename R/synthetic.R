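#' Configuration of the synthetic dataset generator
#'
#' Defines the "true" data-generating process used for simulation studies
#' and tests: annual summer temperatures drive egg-to-larva development
#' times through a linear phenology model; survival then follows the
#' binomial complementary log-log submodel and reproduction the Poisson
#' productivity submodel, both with Normal year effects. Defaults mimic a
#' low-density univoltine moth population censused over 15 years: egg
#' counts in the hundreds fluctuating over one to two orders of magnitude,
#' survival of a few percent, development times of roughly 30-65 days
#' shrinking by about 4.3 days per deg C.
#'
#' @param n_years number of years T (>= 3).
#' @param surv true [survival_params] (year effects drawn, not supplied).
#' @param prod true [productivity_params].
#' @param initial_eggs egg count in year 1 (>= 1).
#' @param start_year first calendar year of the series.
#' @param summer_temp_mean,summer_temp_sd deg C; annual mean temperature
#'   over the development window.
#' @param devtime_intercept,devtime_slope,devtime_sd phenology model
#'   \eqn{d_t = \alpha_d + \beta_d \cdot temp + N(0, sd)} (days, days per
#'   deg C); results are rounded to whole days and floored at
#'   `devtime_min`.
#' @param devtime_min smallest admissible development time (days).
#' @param first_egg_mean_doy,first_egg_sd_doy day-of-year of the first
#'   observed egg (mean and SD).
#' @param winter_min_mean,winter_min_sd deg C; winter minimum temperature.
#' @param snow_days_mean,snow_days_sd days of snow cover (rounded,
#'   clamped to [0, 365]).
#' @param spring_temp_mean,spring_temp_sd deg C; mean May-June temperature.
#' @param daily_temp_sd day-to-day scatter of the daily temperature series
#'   around the annual window mean.
#' @param seed integer seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_years = 15,
                             surv = survival_params(a = 3.8, b = -0.20,
                                                    c = -1.0,
                                                    sigma_eps = 0.16),
                             prod = productivity_params(mu = 4.6, f = -0.41,
                                                        sigma_eta = 0.49),
                             initial_eggs = 374,
                             start_year = 1990,
                             summer_temp_mean = 15, summer_temp_sd = 1.5,
                             devtime_intercept = 109.5,
                             devtime_slope = -4.3, devtime_sd = 7,
                             devtime_min = 5,
                             first_egg_mean_doy = 166,
                             first_egg_sd_doy = 7,
                             winter_min_mean = -12, winter_min_sd = 4,
                             snow_days_mean = 60, snow_days_sd = 25,
                             spring_temp_mean = 11, spring_temp_sd = 1.2,
                             daily_temp_sd = 1.5,
                             seed = 1L) {
  if (n_years < 3) stop("n_years must be >= 3")
  if (initial_eggs < 1) stop("initial_eggs must be >= 1")
  sds <- c(summer_temp_sd, devtime_sd, winter_min_sd, snow_days_sd,
           spring_temp_sd, first_egg_sd_doy, daily_temp_sd)
  if (any(sds < 0)) stop("standard deviations must be >= 0")
  structure(as.list(environment()), class = "generator_config")
}

draw_weather_year <- function(cfg, n) {
  data.frame(
    summer_mean_temp = stats::rnorm(n, cfg$summer_temp_mean,
                                    cfg$summer_temp_sd),
    winter_min_temp = stats::rnorm(n, cfg$winter_min_mean,
                                   cfg$winter_min_sd),
    snow_days = pmin(365, pmax(0, round(stats::rnorm(n, cfg$snow_days_mean,
                                                     cfg$snow_days_sd)))),
    spring_temp = stats::rnorm(n, cfg$spring_temp_mean, cfg$spring_temp_sd))
}

#' Generate synthetic per-year weather covariates
#'
#' Independent Normal draws per year for each weather variable (snow days
#' rounded and clamped to [0, 365]), plus a daily summer temperature
#' series (May 1 - September 30) whose annual mean matches the drawn
#' window temperature, for use with the phenology utilities.
#'
#' @param config a [generator_config].
#' @param seed optional seed overriding `config$seed`.
#' @return list with `weather` (data.frame keyed by year) and
#'   `daily_temps` (data.frame with `date`, `temp`).
#' @export
generate_weather <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(seed)) set.seed(seed)
  years <- config$start_year + seq_len(config$n_years) - 1
  w <- cbind(year = years, draw_weather_year(config, config$n_years))
  daily <- do.call(rbind, lapply(seq_along(years), function(i) {
    dates <- seq(as.Date(paste0(years[i], "-05-01")),
                 as.Date(paste0(years[i], "-09-30")), by = "day")
    data.frame(date = dates,
               temp = w$summer_mean_temp[i] +
                 stats::rnorm(length(dates), 0, config$daily_temp_sd))
  }))
  list(weather = w, daily_temps = daily)
}

#' Generate a complete synthetic dataset
#'
#' Runs the data-generating process forward for `n_years`: each year's
#' summer temperature sets the development time (linear phenology model
#' with Normal noise, rounded to whole days, floored at `devtime_min`);
#' larvae are a binomial draw given cloglog survival with a fresh year
#' effect; next year's eggs are a Poisson draw given per-capita
#' productivity with a fresh year effect, with zero larvae absorbing.
#' Extinct trajectories keep their zeros -- they are genuine observations
#' and [fit()] simply uses the usable years -- but a trajectory providing
#' fewer than 3 usable years or transitions is regenerated under a new
#' sub-seed, up to `max_retries`.
#'
#' The true latent year effects are returned on a side channel, never
#' inside the dataset, so fitting code cannot consume them.
#'
#' @param config a [generator_config].
#' @param seed optional seed overriding `config$seed`.
#' @param max_retries regeneration attempts before giving up.
#' @return list with `data` (a `moth_data`), `latent` (list of the true
#'   `eps`, `eta`, and per-year `summer_temp`), and `attempts`.
#' @export
generate_dataset <- function(config = generator_config(),
                             seed = config$seed, max_retries = 100) {
  stopifnot(inherits(config, "generator_config"))
  for (attempt in seq_len(max_retries)) {
    # sub-seed stream: deterministic in (seed, attempt)
    set.seed(seed + 7919L * (attempt - 1L))
    out <- generate_once(config)
    if (!is.null(out)) {
      out$attempts <- attempt
      return(out)
    }
  }
  stop("population went extinct before 3 transitions in all ", max_retries,
       " attempts; raise initial_eggs or weaken the noise")
}

generate_once <- function(cfg) {
  T <- cfg$n_years
  years <- cfg$start_year + seq_len(T) - 1
  w <- cbind(year = years, draw_weather_year(cfg, T))
  dev <- round(cfg$devtime_intercept +
                 cfg$devtime_slope * w$summer_mean_temp +
                 stats::rnorm(T, 0, cfg$devtime_sd))
  dev <- pmax(dev, cfg$devtime_min)
  first_egg_doy <- round(stats::rnorm(T, cfg$first_egg_mean_doy,
                                      cfg$first_egg_sd_doy))
  first_egg <- as.Date(paste0(years, "-01-01")) + (first_egg_doy - 1)
  first_l5 <- first_egg + dev

  surv <- cfg$surv
  prod <- cfg$prod
  E <- numeric(T); L <- numeric(T)
  eps <- stats::rnorm(T, 0, surv$sigma_eps)
  eta <- stats::rnorm(T, 0, prod$sigma_eta)  # eta[t] drives E_t, t >= 2
  E[1] <- cfg$initial_eggs
  for (t in seq_len(T)) {
    if (E[t] >= 1) {
      s <- survival_prob(surv, E[t], dev[t],
                         summer_temp = w$summer_mean_temp[t],
                         eps_t = eps[t])
      L[t] <- stats::rbinom(1, E[t], s)
    }
    if (t < T) {
      if (L[t] >= 1) {
        wrow <- w[t + 1, ]
        rate <- per_capita_rate(prod, L[t], weather = wrow,
                                eta_t = eta[t + 1])
        E[t + 1] <- stats::rpois(1, L[t] * rate)
      } else {
        E[t + 1] <- 0
      }
    }
  }
  # extinction is kept in the data (the zeros are real observations and
  # the stopping they induce is ignorable for likelihood inference), but
  # the series must still support a fit: >= 3 usable years and transitions
  if (sum(E >= 1) < 3 || sum(L[-T] >= 1) < 3) return(NULL)

  hatched <- L + stats::rbinom(T, E - L, 0.6)  # survivors plus other hatch
  obs <- data.frame(year = years, eggs_laid = E, eggs_hatched = hatched,
                    larvae_l5 = L, first_egg_date = first_egg,
                    first_l5_date = first_l5, dev_time_days = dev)
  data <- moth_data(obs, weather = w, pooled = TRUE)
  list(data = data,
       latent = list(eps = eps, eta = eta[-1],
                     summer_temp = w$summer_mean_temp))
}

#' Fixed 15-year reference dataset
#'
#' A deterministic synthetic dataset generated at the default
#' [generator_config()] truth with a fixed seed; used across the test
#' suite and examples. Identical CSV copies ship in
#' `inst/extdata/counts_synthetic.csv` and
#' `inst/extdata/weather_synthetic.csv`.
#'
#' @return A `moth_data` object with 15 years.
#' @export
fixture_small <- function() {
  generate_dataset(generator_config(seed = 1990L))$data
}
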
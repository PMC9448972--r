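#' Larva-to-next-year-egg productivity submodel parameters
#'
#' Parameters of the Poisson reproduction model
#' \deqn{E_t \sim \mathrm{Poisson}(L_{t-1}\exp(\mu + f \ln L_{t-1}
#' [+ w'x_t] + \eta_t))}
#' spanning the whole pupal overwintering, adult emergence and oviposition
#' period as one lump. \eqn{\eta_t \sim N(0, \sigma_\eta)} is a random year
#' effect; optional weather slopes enter additively in the exponent.
#'
#' @param mu intercept (log per-capita eggs at one larva).
#' @param f slope on log larvae (density dependence of per-capita output).
#' @param sigma_eta standard deviation of the year random effect (> 0).
#' @param eta optional vector of per-transition random effects.
#' @param w_winter_min optional slope per deg C of winter minimum
#'   temperature (winter variant, fitted jointly with `w_snow`).
#' @param w_snow optional slope per day of snow cover (winter variant).
#' @param w_spring optional slope per deg C of mean May-June temperature
#'   (spring variant).
#' @return An object of class `productivity_params`.
#' @export
productivity_params <- function(mu, f, sigma_eta, eta = NULL,
                                w_winter_min = NULL, w_snow = NULL,
                                w_spring = NULL) {
  if (!is.null(sigma_eta) && sigma_eta <= 0) stop("sigma_eta must be > 0")
  structure(list(mu = mu, f = f, sigma_eta = sigma_eta, eta = eta,
                 w_winter_min = w_winter_min, w_snow = w_snow,
                 w_spring = w_spring),
            class = "productivity_params")
}

prod_weather_term <- function(params, weather_row) {
  term <- 0
  grab <- function(col) {
    if (is.null(weather_row) || !col %in% names(weather_row)) {
      stop("weather covariate '", col, "' required by this variant")
    }
    v <- weather_row[[col]]
    if (anyNA(v)) stop("weather covariate '", col, "' has missing values")
    v
  }
  if (!is.null(params$w_winter_min)) {
    term <- term + params$w_winter_min * grab("winter_min_temp")
  }
  if (!is.null(params$w_snow)) term <- term + params$w_snow * grab("snow_days")
  if (!is.null(params$w_spring)) {
    term <- term + params$w_spring * grab("spring_temp")
  }
  term
}

#' Per-capita productivity rate
#'
#' Expected eggs next year per current last-instar larva:
#' \eqn{\exp(\mu + f\ln L [+ w'x] + \eta)}. For `f < 0` the rate falls
#' with larval density, so total expected eggs scale as \eqn{L^{1+f}}.
#'
#' @param params a [productivity_params] object.
#' @param larvae number of last-instar larvae, >= 1 (vectorised).
#' @param weather optional one-row data.frame (or list) carrying the
#'   covariates the variant needs (`winter_min_temp`, `snow_days`,
#'   `spring_temp`).
#' @param eta_t year random effect value (default 0).
#' @return Strictly positive per-capita rate(s).
#' @examples
#' p <- productivity_params(mu = 4.6, f = -0.41, sigma_eta = 0.49)
#' per_capita_rate(p, larvae = 100)  # ~ 15 eggs per larva
#' @export
per_capita_rate <- function(params, larvae, weather = NULL, eta_t = 0) {
  if (any(larvae < 1)) {
    stop("larvae must be >= 1 (zero larvae is the absorbing extinct state; ",
         "see simulate_eggs)")
  }
  lp <- params$mu + params$f * log(larvae) +
    prod_weather_term(params, weather) + eta_t
  exp(pmin(pmax(lp, -700), 700))
}

#' Poisson log-likelihood of the productivity submodel
#'
#' Sum over year transitions \eqn{(L_{t-1}, E_t)} of the Poisson log-pmf of
#' \eqn{E_t} with mean \eqn{L_{t-1}\times} [per_capita_rate()]. The first
#' year's egg count is conditioned on, not modelled.
#'
#' @param params a [productivity_params] object; `params$eta` must be `NULL`
#'   (all zero) or one value per usable transition.
#' @param data a `moth_data` object. Transitions require
#'   \eqn{L_{t-1} \ge 1}; a zero larval count in the fitting data is an
#'   error instructing its exclusion.
#' @return The log-likelihood.
#' @export
loglik_productivity <- function(params, data) {
  tr <- transition_frame(data, need_weather = prod_needs_weather(params))
  eta <- params$eta
  if (is.null(eta)) eta <- rep(0, nrow(tr))
  if (length(eta) != nrow(tr)) {
    stop("params$eta has length ", length(eta), " but ", nrow(tr),
         " transitions are usable")
  }
  rate <- per_capita_rate(params, tr$larvae_prev,
                          weather = tr[, c("winter_min_temp", "snow_days",
                                           "spring_temp")],
                          eta_t = eta)
  sum(stats::dpois(tr$eggs, lambda = tr$larvae_prev * rate, log = TRUE))
}

prod_needs_weather <- function(params) {
  !is.null(params$w_winter_min) || !is.null(params$w_snow) ||
    !is.null(params$w_spring)
}

# transitions (L_{t-1} -> E_t) between consecutive years; with
# subset = TRUE the post-extinction pairs are dropped rather than fatal
transition_frame <- function(data, need_weather = FALSE, subset = FALSE) {
  stopifnot(inherits(data, "moth_data"))
  obs <- data$observations
  n <- nrow(obs)
  if (n < 2) stop("at least 2 years needed to form a transition")
  consec <- diff(obs$year) == 1
  from <- which(consec)
  if (length(from) == 0) stop("no consecutive-year transitions in the data")
  Lprev <- obs$larvae_l5[from]
  if (any(Lprev == 0)) {
    if (subset) {
      from <- from[Lprev >= 1]
      Lprev <- obs$larvae_l5[from]
      if (length(from) == 0) stop("no usable transitions in the data")
    } else {
      stop("larvae_l5 = 0 in year(s) ",
           paste(obs$year[from][Lprev == 0], collapse = ", "),
           "; exclude these transitions before fitting the productivity ",
           "submodel (zero larvae is the absorbing extinct state)")
    }
  }
  tr <- data.frame(year = obs$year[from + 1], larvae_prev = Lprev,
                   eggs = obs$eggs_laid[from + 1],
                   winter_min_temp = NA_real_, snow_days = NA_real_,
                   spring_temp = NA_real_)
  if (need_weather) {
    if (is.null(data$weather)) stop("weather table required by this variant")
    idx <- match(tr$year, data$weather$year)
    for (col in c("winter_min_temp", "snow_days", "spring_temp")) {
      if (col %in% names(data$weather)) tr[[col]] <- data$weather[[col]][idx]
    }
  }
  tr
}

#' Simulate next-year egg counts from the productivity submodel
#'
#' Draws \eqn{E \sim \mathrm{Poisson}(L \times} [per_capita_rate()]
#' \eqn{)}. A zero larval count deterministically yields zero eggs: local
#' extinction is absorbing (no immigration is modelled).
#'
#' @inheritParams per_capita_rate
#' @param larvae number of last-instar larvae, >= 0.
#' @param eta_t numeric year effect, or `"draw"` to sample it from
#'   \eqn{N(0, \sigma_\eta)}.
#' @param seed optional integer seed.
#' @return Integer egg count(s).
#' @export
simulate_eggs <- function(params, larvae, weather = NULL, eta_t = 0,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(larvae < 0)) stop("larvae must be >= 0")
  n <- length(larvae)
  if (identical(eta_t, "draw")) {
    eta_t <- stats::rnorm(n, 0, params$sigma_eta)
  }
  out <- integer(n)
  alive <- larvae >= 1
  if (any(alive)) {
    eta_alive <- if (length(eta_t) == 1) rep(eta_t, n) else eta_t
    rate <- per_capita_rate(params, larvae[alive], weather,
                            eta_t = eta_alive[alive])
    out[alive] <- stats::rpois(sum(alive), lambda = larvae[alive] * rate)
  }
  out
}
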
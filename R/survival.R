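#' Egg-to-larva survival submodel parameters
#'
#' Parameters of the binomial survival model with complementary log-log
#' link: \deqn{s_t = \exp(-\exp(-(a + b \ln E_t + c \ln d_t
#' [+ g_{temp} T_t] + \epsilon_t)))}
#' where \eqn{E_t} is the number of eggs laid, \eqn{d_t} the egg-to-larva
#' development time in days, \eqn{T_t} an optional summer mean temperature,
#' and \eqn{\epsilon_t \sim N(0, \sigma_\epsilon)} a random year effect.
#' Natural logarithms throughout; the intercept scale depends on that
#' convention.
#'
#' @param a intercept for the hazard rate (dimensionless).
#' @param b slope on log eggs laid (density dependence; negative values mean
#'   survival falls with density).
#' @param c slope on log development time. Under the Weibull-hazard reading
#'   the hazard shape is `-c`; `c = -1` is a constant per-day hazard.
#' @param sigma_eps standard deviation of the year random effect (> 0).
#' @param eps optional vector of per-year random effects.
#' @param g_temp optional slope for a direct summer mean temperature effect
#'   (per deg C), used by the `summer_temp` and `summer_temp_devtime`
#'   model variants.
#' @return An object of class `survival_params`.
#' @export
survival_params <- function(a, b, c = NULL, sigma_eps, eps = NULL,
                            g_temp = NULL) {
  if (!is.null(sigma_eps) && sigma_eps <= 0) stop("sigma_eps must be > 0")
  structure(list(a = a, b = b, c = c, sigma_eps = sigma_eps, eps = eps,
                 g_temp = g_temp),
            class = "survival_params")
}

# linear predictor of the cloglog survival model, clipped to +-700 so that
# exp(-lp) never overflows a double
surv_linpred <- function(params, eggs, dev_time, summer_temp = NULL,
                         eps_t = 0) {
  if (any(eggs < 1)) stop("eggs must be >= 1 (log undefined at 0)")
  if (!is.null(params$c) && any(dev_time <= 0)) {
    stop("dev_time must be > 0")
  }
  lp <- params$a + params$b * log(eggs) + eps_t
  if (!is.null(params$c)) lp <- lp + params$c * log(dev_time)
  if (!is.null(params$g_temp)) {
    if (is.null(summer_temp)) {
      stop("summer_temp required when g_temp is set")
    }
    lp <- lp + params$g_temp * summer_temp
  }
  pmin(pmax(lp, -700), 700)
}

#' Survival probability over the egg-larval development window
#'
#' Evaluates \eqn{s = \exp(-\exp(-(a + b\ln E + c\ln d [+ g T] +
#' \epsilon)))}, the probability that an egg survives to the last larval
#' instar. Equivalent to survival to time \eqn{d} under a Weibull
#' cumulative hazard \eqn{\Lambda(d) = \lambda d^{-c}} with
#' \eqn{\lambda = \exp(-(a + b\ln E + gT + \epsilon))}; see
#' [hazard_shape()].
#'
#' @param params a [survival_params] object.
#' @param eggs number of eggs laid, >= 1 (vectorised).
#' @param dev_time development time in days, > 0 (vectorised). Ignored when
#'   `params$c` is `NULL` (direct-temperature-only variant).
#' @param summer_temp optional summer mean temperature (deg C), required when
#'   `params$g_temp` is set.
#' @param eps_t year random effect value (default 0).
#' @return Survival probability, strictly inside (0, 1) for finite inputs
#'   within the numerical clipping range.
#' @examples
#' p <- survival_params(a = 3.8, b = -0.20, c = -1.0, sigma_eps = 0.16)
#' survival_prob(p, eggs = 374, dev_time = 42)  # ~ 0.046
#' @export
survival_prob <- function(params, eggs, dev_time, summer_temp = NULL,
                          eps_t = 0) {
  lp <- surv_linpred(params, eggs, dev_time, summer_temp, eps_t)
  exp(-exp(-lp))
}

#' Weibull hazard shape implied by the survival model
#'
#' The complementary log-log link in log development time means survival to
#' time \eqn{d} satisfies \eqn{-\ln s(d) = \lambda d^{k}} with shape
#' \eqn{k = -c}: the per-day hazard is \eqn{\lambda k d^{k-1}}, a power
#' function of time. `c = -1` (shape 1) is a constant per-day hazard;
#' `c = -2` (shape 2) a hazard increasing linearly in time; `c = 0`
#' (shape 0) removes any dependence on the window length.
#'
#' Sign convention: the slope is reported here as it enters the linear
#' predictor (negative when longer windows lower survival); some summaries
#' quote the magnitude \eqn{|c|} instead, which equals the shape.
#'
#' @param params a [survival_params] object (or a single numeric `c`).
#' @return The Weibull shape parameter `-c`.
#' @export
hazard_shape <- function(params) {
  cc <- if (inherits(params, "survival_params")) params$c else params
  if (is.null(cc)) stop("model variant has no development-time slope c")
  -cc
}

# log(1 - exp(-h)) computed stably for h > 0
log1mexp <- function(h) {
  ifelse(h > log(2), log1p(-exp(-h)), log(-expm1(-h)))
}

#' Binomial log-likelihood of the survival submodel
#'
#' Sum over years of the log-probability \eqn{L_t \sim
#' \mathrm{Binomial}(E_t, s_t)}. The binomial accounts for demographic
#' stochasticity; the year effects `params$eps` (default all zero) carry
#' the environmental component. Computed via the cumulative hazard
#' (\eqn{\log s = -e^{-lp}}, \eqn{\log(1-s)} by `log1p`/`expm1`) so it is
#' finite and accurate even for survival very close to 0 or 1.
#'
#' @param params a [survival_params] object; `params$eps` must be `NULL`
#'   (all zero) or one value per usable year.
#' @param data a `moth_data` object; years enter when they have
#'   `eggs_laid >= 1` and, unless the variant drops development time, a
#'   positive `dev_time_days`.
#' @return The log-likelihood (a single finite number).
#' @export
loglik_survival <- function(params, data) {
  sd <- survival_frame(data, need_devtime = !is.null(params$c),
                       need_temp = !is.null(params$g_temp))
  eps <- params$eps
  if (is.null(eps)) eps <- rep(0, nrow(sd))
  if (length(eps) != nrow(sd)) {
    stop("params$eps has length ", length(eps), " but ", nrow(sd),
         " years are usable")
  }
  lp <- surv_linpred(params, sd$eggs, sd$dev_time, sd$temp, eps)
  h <- exp(-lp)                      # cumulative hazard; -log survival
  sum(lchoose(sd$eggs, sd$larvae) - sd$larvae * h +
        (sd$eggs - sd$larvae) * log1mexp(h))
}

# extract the per-year vectors the survival submodel consumes; with
# subset = TRUE the empty (extinct) years are dropped rather than fatal
survival_frame <- function(data, need_devtime = TRUE, need_temp = FALSE,
                           subset = FALSE) {
  stopifnot(inherits(data, "moth_data"))
  obs <- data$observations
  if (any(obs$eggs_laid == 0)) {
    if (subset) {
      obs <- obs[obs$eggs_laid >= 1, , drop = FALSE]
    } else {
      stop("year(s) ", paste(obs$year[obs$eggs_laid == 0], collapse = ", "),
           " have eggs_laid = 0; exclude them before fitting the survival ",
           "submodel (log egg density is undefined)")
    }
  }
  if (any(obs$larvae_l5 > obs$eggs_laid)) {
    stop("larvae_l5 > eggs_laid in year(s) ",
         paste(obs$year[obs$larvae_l5 > obs$eggs_laid], collapse = ", "))
  }
  dev_time <- if ("dev_time_days" %in% names(obs)) obs$dev_time_days else
    rep(NA_real_, nrow(obs))
  if (need_devtime && any(is.na(dev_time) | dev_time <= 0)) {
    stop("positive dev_time_days required for every year; missing or ",
         "non-positive in year(s) ",
         paste(obs$year[is.na(dev_time) | dev_time <= 0], collapse = ", "))
  }
  temp <- rep(NA_real_, nrow(obs))
  if (need_temp) {
    if (is.null(data$weather) ||
        !"summer_mean_temp" %in% names(data$weather)) {
      stop("summer_mean_temp weather covariate required for this variant")
    }
    temp <- data$weather$summer_mean_temp[match(obs$year, data$weather$year)]
    if (anyNA(temp)) {
      stop("summer_mean_temp missing for year(s) ",
           paste(obs$year[is.na(temp)], collapse = ", "))
    }
  }
  data.frame(year = obs$year, eggs = obs$eggs_laid, larvae = obs$larvae_l5,
             dev_time = dev_time, temp = temp)
}

#' Simulate larval counts from the survival submodel
#'
#' Draws \eqn{L \sim \mathrm{Binomial}(E, s)} with \eqn{s} from
#' [survival_prob()]. The year effect can be supplied or freshly drawn from
#' its \eqn{N(0, \sigma_\epsilon)} distribution.
#'
#' @inheritParams survival_prob
#' @param eps_t numeric year effect, or the string `"draw"` to sample it.
#' @param seed optional integer seed for reproducibility.
#' @return Integer larval count(s), the same length as `eggs`.
#' @export
simulate_larvae <- function(params, eggs, dev_time, summer_temp = NULL,
                            eps_t = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- max(length(eggs), length(dev_time))
  if (identical(eps_t, "draw")) {
    eps_t <- stats::rnorm(n, 0, params$sigma_eps)
  }
  s <- survival_prob(params, eggs, dev_time, summer_temp, eps_t)
  stats::rbinom(n, size = eggs, prob = s)
}
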
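#' MCMC model configuration
#'
#' Settings for fitting the joint two-stage model. The fixed effects get
#' vague Uniform(-B, B) priors and the random-effect standard deviations
#' half-Cauchy(0, scale) priors; per-year effects are Normal(0, sigma).
#'
#' @param variant one of `"base"`, `"winter"` (adds winter minimum
#'   temperature and snow-day slopes to productivity), `"spring"` (adds a
#'   May-June temperature slope to productivity), `"summer_temp"` (replaces
#'   the development-time term in survival with a direct summer-temperature
#'   slope), `"summer_temp_devtime"` (keeps both).
#' @param n_chains number of MCMC chains (>= 2).
#' @param n_iterations iterations per chain, including warmup.
#' @param n_warmup adaptation iterations discarded from each chain.
#' @param thin keep every `thin`-th post-warmup draw.
#' @param seed integer seed controlling the whole fit.
#' @param prior_fixed_bound half-width B of the uniform priors on fixed
#'   effects.
#' @param prior_sd_scale scale of the half-Cauchy priors on
#'   `sigma_eps` and `sigma_eta`.
#' @param rhat_threshold convergence gate; any parameter at or above it
#'   flags the fit as not converged (with a warning, never silently).
#' @return An object of class `model_config`.
#' @export
model_config <- function(variant = c("base", "winter", "spring",
                                     "summer_temp", "summer_temp_devtime"),
                         n_chains = 4, n_iterations = 100000,
                         n_warmup = NULL, thin = 10, seed = 1,
                         prior_fixed_bound = 10, prior_sd_scale = 2.5,
                         rhat_threshold = 1.01) {
  variant <- match.arg(variant)
  if (is.null(n_warmup)) n_warmup <- floor(n_iterations / 2)
  if (n_chains < 2) stop("n_chains must be >= 2")
  if (n_warmup >= n_iterations) stop("n_warmup must be < n_iterations")
  if (thin < 1) stop("thin must be >= 1")
  if (prior_fixed_bound <= 0 || prior_sd_scale <= 0) {
    stop("prior bounds must be positive")
  }
  structure(list(variant = variant, n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 n_warmup = as.integer(n_warmup), thin = as.integer(thin),
                 seed = as.integer(seed),
                 prior_fixed_bound = prior_fixed_bound,
                 prior_sd_scale = prior_sd_scale,
                 rhat_threshold = rhat_threshold),
            class = "model_config")
}

variant_uses_devtime <- function(variant) variant != "summer_temp"
variant_uses_temp <- function(variant) {
  variant %in% c("summer_temp", "summer_temp_devtime")
}
variant_prod_covariates <- function(variant) {
  switch(variant,
         winter = c("w_winter_min", "w_snow"),
         spring = "w_spring",
         character(0))
}
prod_covariate_column <- c(w_winter_min = "winter_min_temp",
                           w_snow = "snow_days",
                           w_spring = "spring_temp")

surv_fixed_names <- function(variant) {
  c("a", "b",
    if (variant_uses_devtime(variant)) "c",
    if (variant_uses_temp(variant)) "g_temp")
}
prod_fixed_names <- function(variant) {
  c("mu", "f", variant_prod_covariates(variant))
}

#' Joint log-prior density
#'
#' Sum of the log prior densities of every parameter of the chosen variant:
#' Uniform(-B, B) for each fixed effect, half-Cauchy(0, scale) for the
#' random-effect standard deviations, and Normal(0, sigma) for each
#' supplied per-year effect. Returns `-Inf` outside the support.
#'
#' @param surv a [survival_params] object (with `eps` optionally set).
#' @param prod a [productivity_params] object (with `eta` optionally set).
#' @param config a [model_config].
#' @return The log prior density.
#' @export
log_prior <- function(surv, prod, config) {
  B <- config$prior_fixed_bound
  fixed <- c(unlist(surv[surv_fixed_names(config$variant)]),
             unlist(prod[prod_fixed_names(config$variant)]))
  if (length(fixed) != length(surv_fixed_names(config$variant)) +
        length(prod_fixed_names(config$variant))) {
    stop("parameter objects lack fixed effects required by variant '",
         config$variant, "'")
  }
  if (any(abs(fixed) >= B)) return(-Inf)
  lp <- length(fixed) * (-log(2 * B))
  for (sigma in c(surv$sigma_eps, prod$sigma_eta)) {
    if (sigma <= 0) return(-Inf)
    lp <- lp + log(2) + stats::dcauchy(sigma, 0, config$prior_sd_scale,
                                       log = TRUE)
  }
  if (!is.null(surv$eps)) {
    lp <- lp + sum(stats::dnorm(surv$eps, 0, surv$sigma_eps, log = TRUE))
  }
  if (!is.null(prod$eta)) {
    lp <- lp + sum(stats::dnorm(prod$eta, 0, prod$sigma_eta, log = TRUE))
  }
  lp
}

#' Joint log-posterior density
#'
#' `log_prior + loglik_survival + loglik_productivity` for the chosen
#' variant. The first year's egg count is conditioned on, not modelled.
#' This reference implementation defines the target distribution; the
#' compiled sampler used by [fit()] targets exactly this function.
#'
#' @inheritParams log_prior
#' @param data a `moth_data` object passing both submodels' preconditions.
#' @return The unnormalised log posterior density.
#' @export
log_posterior <- function(surv, prod, data, config) {
  if (nrow(data$observations) < 2) {
    stop("dataset too small: need at least one survival year and one ",
         "transition")
  }
  log_prior(surv, prod, config) +
    loglik_survival(surv, data) +
    loglik_productivity(prod, data)
}

#' Split-chain potential scale reduction factor (R-hat)
#'
#' Gelman-Rubin convergence diagnostic. With `split = TRUE` (default) each
#' chain is split in half so that trending chains are flagged even when
#' their pooled means agree; `split = FALSE` gives the classic form, for
#' which two identical stationary chains yield \eqn{\sqrt{(n-1)/n}}.
#'
#' @param draws a matrix of draws, iterations in rows and chains in
#'   columns (>= 2 chains, >= 4 draws each).
#' @param split logical; split each chain in half first.
#' @return The scalar R-hat.
#' @export
rhat <- function(draws, split = TRUE) {
  draws <- as.matrix(draws)
  if (ncol(draws) < 2) stop("need at least 2 chains")
  if (nrow(draws) < 4) stop("need at least 4 draws per chain")
  if (split) {
    half <- floor(nrow(draws) / 2)
    draws <- cbind(draws[seq_len(half), , drop = FALSE],
                   draws[nrow(draws) - half + seq_len(half), , drop = FALSE])
  }
  n <- nrow(draws)
  m <- ncol(draws)
  means <- colMeans(draws)
  vars <- apply(draws, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Highest posterior density interval
#'
#' The shortest contiguous interval containing at least `mass` of the
#' sample: among all windows of `ceiling(mass * n)` consecutive sorted
#' values, the narrowest one.
#'
#' @param samples numeric vector of at least 20 draws.
#' @param mass interval probability mass, in (0, 1); default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(samples, mass = 0.95) {
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n < 20) stop("need at least 20 samples for an HPD interval")
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)")
  x <- sort(samples)
  m <- ceiling(mass * n)
  starts <- seq_len(n - m + 1)
  widths <- x[starts + m - 1] - x[starts]
  i <- starts[which.min(widths)]
  c(lower = x[i], upper = x[i + m - 1])
}

# ---- internal: data packing shared with the compiled sampler ----

pack_fit_data <- function(data, config) {
  variant <- config$variant
  sf <- survival_frame(data, need_devtime = variant_uses_devtime(variant),
                       need_temp = variant_uses_temp(variant),
                       subset = TRUE)
  covs <- variant_prod_covariates(variant)
  tr <- transition_frame(data, need_weather = length(covs) > 0,
                         subset = TRUE)
  if (nrow(sf) < 3 || nrow(tr) < 3) {
    stop("need at least 3 usable survival years and 3 transitions to fit")
  }
  Xw <- matrix(0, nrow(tr), length(covs))
  if (length(covs) > 0) {
    for (j in seq_along(covs)) {
      col <- prod_covariate_column[[covs[j]]]
      v <- tr[[col]]
      if (anyNA(v)) {
        stop("weather covariate '", col, "' missing for transition year(s) ",
             paste(tr$year[is.na(v)], collapse = ", "))
      }
      Xw[, j] <- v
    }
  }
  list(E = sf$eggs, L = sf$larvae, logE = log(sf$eggs),
       logd = if (variant_uses_devtime(variant)) log(sf$dev_time) else
         numeric(nrow(sf)),
       temp = if (variant_uses_temp(variant)) sf$temp else numeric(nrow(sf)),
       use_d = as.integer(variant_uses_devtime(variant)),
       use_temp = as.integer(variant_uses_temp(variant)),
       Lprev = tr$larvae_prev, logLprev = log(tr$larvae_prev),
       Eobs = tr$eggs, Xw = Xw,
       B = config$prior_fixed_bound, scale = config$prior_sd_scale,
       surv_years = sf$year, trans_years = tr$year)
}

param_names_for <- function(dat, config) {
  c(surv_fixed_names(config$variant), "sigma_eps",
    paste0("eps[", dat$surv_years, "]"),
    prod_fixed_names(config$variant), "sigma_eta",
    paste0("eta[", dat$trans_years, "]"))
}

# pack parameter objects into the flat vector the compiled code consumes
pack_theta <- function(surv, prod, dat, config) {
  eps <- surv$eps
  if (is.null(eps)) eps <- rep(0, length(dat$surv_years))
  eta <- prod$eta
  if (is.null(eta)) eta <- rep(0, length(dat$trans_years))
  as.numeric(c(unlist(surv[surv_fixed_names(config$variant)]),
               surv$sigma_eps, eps,
               unlist(prod[prod_fixed_names(config$variant)]),
               prod$sigma_eta, eta))
}

unpack_theta <- function(theta, dat, config) {
  sn <- surv_fixed_names(config$variant)
  pn <- prod_fixed_names(config$variant)
  Ty <- length(dat$surv_years)
  Tr <- length(dat$trans_years)
  i <- 0
  sfix <- theta[i + seq_along(sn)]; i <- i + length(sn)
  sigma_eps <- theta[i + 1]; i <- i + 1
  eps <- theta[i + seq_len(Ty)]; i <- i + Ty
  pfix <- theta[i + seq_along(pn)]; i <- i + length(pn)
  sigma_eta <- theta[i + 1]; i <- i + 1
  eta <- theta[i + seq_len(Tr)]
  surv <- survival_params(a = sfix[[1]], b = sfix[[2]],
                          c = if ("c" %in% sn) sfix[[match("c", sn)]],
                          sigma_eps = sigma_eps, eps = eps,
                          g_temp = if ("g_temp" %in% sn)
                            sfix[[match("g_temp", sn)]])
  prod <- productivity_params(mu = pfix[[1]], f = pfix[[2]],
                              sigma_eta = sigma_eta, eta = eta)
  for (w in variant_prod_covariates(config$variant)) {
    prod[[w]] <- pfix[[match(w, pn)]]
  }
  list(surv = surv, prod = prod)
}
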
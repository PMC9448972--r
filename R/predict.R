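#' One-step forward predictive distributions
#'
#' Posterior predictive medians and central intervals for each predictable
#' year, integrating over posterior parameter draws, freshly drawn year
#' effects (\eqn{\epsilon, \eta \sim N(0, \sigma)}; predictions are for
#' years whose realised effects are unobserved), and demographic
#' (binomial / Poisson) noise.
#'
#' Modes: `"L_from_E"` predicts larvae from the same year's eggs;
#' `"E_from_L"` predicts eggs from the previous year's larvae;
#' `"E_from_E"` and `"L_from_L"` chain both submodels through the
#' unobserved intermediate stage, with extinction absorbing at zero.
#'
#' @param fit a `moth_fit`.
#' @param data a `moth_data` object; defaults to the fitted data.
#' @param mode one of `"E_from_L"`, `"E_from_E"`, `"L_from_E"`,
#'   `"L_from_L"`.
#' @param probs predictive quantiles to report (default 25/50/75\%).
#' @param n_draws posterior draws used (subsampled without replacement if
#'   fewer than available).
#' @param seed optional integer seed.
#' @param return_draws attach the raw predictive draws per year as the
#'   `"draws"` attribute (a named list), for downstream distributional
#'   checks.
#' @return data.frame with `year`, `observed`, one column per requested
#'   quantile (`q25`, `q50`, `q75`, ...), and `mean`.
#' @export
one_step_predict <- function(fit, data = fit$data,
                             mode = c("E_from_L", "E_from_E", "L_from_E",
                                      "L_from_L"),
                             probs = c(0.25, 0.5, 0.75), n_draws = 2000,
                             seed = NULL, return_draws = FALSE) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  cfg <- fit$config
  hp <- posterior_draws(fit, fit$hyper_names)
  n_av <- nrow(hp)
  idx <- if (n_av > n_draws) sample.int(n_av, n_draws) else seq_len(n_av)
  hp <- hp[idx, , drop = FALSE]
  nd <- nrow(hp)

  sf <- survival_frame(data,
                       need_devtime = variant_uses_devtime(cfg$variant),
                       need_temp = variant_uses_temp(cfg$variant),
                       subset = TRUE)
  tr <- transition_frame(data, need_weather =
                           length(variant_prod_covariates(cfg$variant)) > 0,
                         subset = TRUE)

  pred_surv <- function(E, d, temp) {
    eps <- stats::rnorm(nd, 0, hp[, "sigma_eps"])
    lp <- hp[, "a"] + hp[, "b"] * log(E) + eps
    if (variant_uses_devtime(cfg$variant)) lp <- lp + hp[, "c"] * log(d)
    if (variant_uses_temp(cfg$variant)) lp <- lp + hp[, "g_temp"] * temp
    s <- exp(-exp(-pmin(pmax(lp, -700), 700)))
    stats::rbinom(nd, E, s)
  }
  pred_surv_vecE <- function(E, d, temp) {
    # per-draw egg inputs (used when chaining through a predicted stage)
    out <- integer(nd)
    alive <- E >= 1
    if (any(alive)) {
      eps <- stats::rnorm(sum(alive), 0, hp[alive, "sigma_eps"])
      lp <- hp[alive, "a"] + hp[alive, "b"] * log(E[alive]) + eps
      if (variant_uses_devtime(cfg$variant)) {
        lp <- lp + hp[alive, "c"] * log(d)
      }
      if (variant_uses_temp(cfg$variant)) {
        lp <- lp + hp[alive, "g_temp"] * temp
      }
      s <- exp(-exp(-pmin(pmax(lp, -700), 700)))
      out[alive] <- stats::rbinom(sum(alive), E[alive], s)
    }
    out
  }
  wterm <- function(row) {
    out <- 0
    for (w in variant_prod_covariates(cfg$variant)) {
      out <- out + hp[, w] * row[[prod_covariate_column[[w]]]]
    }
    out
  }
  pred_prod <- function(L, wrow) {
    out <- integer(nd)
    if (length(L) == 1) L <- rep(L, nd)
    alive <- L >= 1
    if (any(alive)) {
      eta <- stats::rnorm(sum(alive), 0, hp[alive, "sigma_eta"])
      wt <- wterm(wrow)
      if (length(wt) > 1) wt <- wt[alive]
      lq <- hp[alive, "mu"] + hp[alive, "f"] * log(L[alive]) + wt + eta
      lam <- L[alive] * exp(pmin(pmax(lq, -700), 700))
      out[alive] <- stats::rpois(sum(alive), lam)
    }
    out
  }

  rows <- list()
  if (mode == "L_from_E") {
    for (i in seq_len(nrow(sf))) {
      rows[[length(rows) + 1]] <-
        list(year = sf$year[i], observed = sf$larvae[i],
             draws = pred_surv(sf$eggs[i], sf$dev_time[i], sf$temp[i]))
    }
  } else {
    obs <- data$observations
    for (i in seq_len(nrow(tr))) {
      yr <- tr$year[i]
      j <- match(yr, sf$year)          # survival inputs of year t
      jp <- match(yr - 1, sf$year)     # survival inputs of year t-1
      wrow <- tr[i, ]
      if (mode == "E_from_L") {
        dr <- pred_prod(tr$larvae_prev[i], wrow)
        observed <- tr$eggs[i]
      } else if (mode == "E_from_E") {
        if (is.na(jp)) next
        Lstar <- pred_surv(sf$eggs[jp], sf$dev_time[jp], sf$temp[jp])
        dr <- pred_prod(Lstar, wrow)
        observed <- tr$eggs[i]
      } else { # L_from_L
        if (is.na(j)) next
        Estar <- pred_prod(tr$larvae_prev[i], wrow)
        dr <- pred_surv_vecE(Estar, sf$dev_time[j], sf$temp[j])
        observed <- obs$larvae_l5[match(yr, obs$year)]
      }
      rows[[length(rows) + 1]] <- list(year = yr, observed = observed,
                                       draws = dr)
    }
  }
  if (length(rows) == 0) stop("no predictable years for mode ", mode)
  out <- data.frame(year = vapply(rows, `[[`, 0, "year"),
                    observed = vapply(rows, `[[`, 0, "observed"))
  for (p in probs) {
    out[[paste0("q", round(100 * p))]] <-
      vapply(rows, function(r) stats::quantile(r$draws, p, names = FALSE), 0)
  }
  out$mean <- vapply(rows, function(r) mean(r$draws), 0)
  if (return_draws) {
    attr(out, "draws") <- stats::setNames(lapply(rows, `[[`, "draws"),
                                          out$year)
  }
  out
}

#' Posterior predictive p-values
#'
#' Goodness-of-fit checks comparing observed summary statistics (mean, SD,
#' minimum and maximum of the egg and larval series) with their
#' distribution over replicate datasets simulated forward from the fitted
#' model: each replicate redraws parameters from the posterior, year
#' effects from their Normal distributions, and full demographic noise,
#' propagating from the observed first-year egg count with the observed
#' development times and weather covariates. The p-value is the upper-tail
#' probability \eqn{\Pr(T_{rep} \ge T_{obs})}; values outside (0.05, 0.95)
#' flag misfit. Egg statistics use years 2 onward (the first year's egg
#' count is conditioned on); larval statistics use all years.
#'
#' @param fit a `moth_fit`.
#' @param data a `moth_data` object; defaults to the fitted data.
#' @param n_rep number of replicate datasets.
#' @param seed optional integer seed.
#' @param band pass band for the flag (default `c(0.05, 0.95)`).
#' @return data.frame with `stage`, `statistic`, `observed`, `p_value`,
#'   `pass`.
#' @export
posterior_predictive_pvalues <- function(fit, data = fit$data, n_rep = 1000,
                                         seed = NULL,
                                         band = c(0.05, 0.95)) {
  if (!is.null(seed)) set.seed(seed)
  sf <- survival_frame(
    data, need_devtime = variant_uses_devtime(fit$config$variant),
    need_temp = variant_uses_temp(fit$config$variant), subset = TRUE)
  H <- nrow(sf)
  weather <- if (!is.null(data$weather)) {
    data$weather[match(sf$year, data$weather$year), , drop = FALSE]
  } else NULL
  sim <- simulate_trajectories(fit, initial_eggs = sf$eggs[1],
                               dev_times = sf$dev_time,
                               weather = weather,
                               summer_temps = sf$temp,
                               n_reps = n_rep)
  stats_of <- function(x) c(mean = mean(x), sd = stats::sd(x),
                            min = min(x), max = max(x))
  obs_eggs <- sf$eggs[-1]
  obs_larv <- data$observations$larvae_l5[match(sf$year,
                                                data$observations$year)]
  rep_eggs <- sim$trajectories$eggs[, -1, drop = FALSE]
  rep_larv <- sim$trajectories$larvae
  out <- list()
  for (stage in c("eggs", "larvae")) {
    obs_stat <- stats_of(if (stage == "eggs") obs_eggs else obs_larv)
    repmat <- if (stage == "eggs") rep_eggs else rep_larv
    rep_stats <- t(apply(repmat, 1, stats_of))
    for (st in names(obs_stat)) {
      p <- mean(rep_stats[, st] >= obs_stat[[st]])
      out[[length(out) + 1]] <-
        data.frame(stage = stage, statistic = st,
                   observed = obs_stat[[st]], p_value = p,
                   pass = p > band[1] & p < band[2])
    }
  }
  do.call(rbind, out)
}

#' Stochastic multi-year trajectory simulation
#'
#' Propagates the two-stage model forward year by year
#' (\eqn{E \to L \to E'}) from a starting egg count, with parameter
#' uncertainty (one posterior draw per replicate when a fit is supplied),
#' environmental noise (fresh \eqn{\epsilon_t, \eta_t}) and demographic
#' noise (binomial / Poisson draws). Extinction is absorbing: once a
#' replicate hits zero it stays at zero.
#'
#' @param object a `moth_fit`, or a list `list(surv = survival_params,
#'   prod = productivity_params)` of fixed parameters.
#' @param initial_eggs egg count in the first simulated year (>= 0).
#' @param dev_times vector of per-year development times (days); its length
#'   sets the simulation horizon.
#' @param weather optional data.frame with one row per simulated year
#'   (columns among `winter_min_temp`, `snow_days`, `spring_temp`), needed
#'   by covariate variants. Row `t` applies to the transition into year
#'   `t` (the winter/spring preceding that year's oviposition).
#' @param summer_temps optional per-year summer mean temperatures for the
#'   direct-temperature survival variants.
#' @param n_reps number of replicate trajectories.
#' @param seed optional integer seed.
#' @param demographic include binomial/Poisson noise; with `FALSE` the
#'   deterministic expectations are propagated (no rounding).
#' @param environmental include random year effects.
#' @return An object of class `moth_sim`: `trajectories` (list of
#'   `eggs` and `larvae` replicate-by-year matrices), `extinct_fraction`,
#'   and `quantile_bands` (per year and stage: mean, median, 50\%
#'   interval).
#' @export
simulate_trajectories <- function(object, initial_eggs, dev_times,
                                  weather = NULL, summer_temps = NULL,
                                  n_reps = 1000, seed = NULL,
                                  demographic = TRUE, environmental = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  if (initial_eggs < 0) stop("initial_eggs must be >= 0")
  H <- length(dev_times)
  if (H < 1) stop("dev_times must cover at least one year")
  if (!is.null(weather) && nrow(weather) < H) {
    stop("weather must have one row per simulated year (horizon ", H, ")")
  }

  if (inherits(object, "moth_fit")) {
    variant <- object$config$variant
    hp <- posterior_draws(object, object$hyper_names)
    idx <- sample.int(nrow(hp), n_reps, replace = TRUE)
    hp <- hp[idx, , drop = FALSE]
    getp <- function(nm) if (nm %in% colnames(hp)) hp[, nm] else NULL
  } else {
    surv <- object$surv
    prod <- object$prod
    variant <- if (!is.null(surv$g_temp) && is.null(surv$c)) "summer_temp"
      else if (!is.null(surv$g_temp)) "summer_temp_devtime"
      else if (!is.null(prod$w_winter_min)) "winter"
      else if (!is.null(prod$w_spring)) "spring" else "base"
    flat <- c(a = surv$a, b = surv$b, c = surv$c, g_temp = surv$g_temp,
              sigma_eps = surv$sigma_eps, mu = prod$mu, f = prod$f,
              sigma_eta = prod$sigma_eta,
              w_winter_min = prod$w_winter_min, w_snow = prod$w_snow,
              w_spring = prod$w_spring)
    getp <- function(nm) if (nm %in% names(flat)) rep(flat[[nm]], n_reps)
      else NULL
  }
  a <- getp("a"); b <- getp("b"); cc <- getp("c"); g <- getp("g_temp")
  se <- getp("sigma_eps"); mu <- getp("mu"); f <- getp("f")
  sh <- getp("sigma_eta")
  wcoef <- list(w_winter_min = getp("w_winter_min"),
                w_snow = getp("w_snow"), w_spring = getp("w_spring"))
  if (variant_uses_temp(variant) && is.null(summer_temps)) {
    stop("summer_temps required for variant '", variant, "'")
  }

  eggs <- matrix(0, n_reps, H)
  larv <- matrix(0, n_reps, H)
  E <- rep(as.numeric(initial_eggs), n_reps)
  for (t in seq_len(H)) {
    eggs[, t] <- E
    alive <- E >= 1
    L <- numeric(n_reps)
    if (any(alive)) {
      eps <- if (environmental) stats::rnorm(sum(alive), 0, se[alive]) else 0
      lp <- a[alive] + b[alive] * log(E[alive]) + eps
      if (variant_uses_devtime(variant)) {
        lp <- lp + cc[alive] * log(dev_times[t])
      }
      if (variant_uses_temp(variant)) lp <- lp + g[alive] * summer_temps[t]
      s <- exp(-exp(-pmin(pmax(lp, -700), 700)))
      L[alive] <- if (demographic) {
        stats::rbinom(sum(alive), round(E[alive]), s)
      } else E[alive] * s
    }
    larv[, t] <- L
    if (t < H) {
      alive <- L >= 1
      En <- numeric(n_reps)
      if (any(alive)) {
        eta <- if (environmental) stats::rnorm(sum(alive), 0, sh[alive])
          else 0
        lq <- mu[alive] + f[alive] * log(L[alive]) + eta
        for (w in names(wcoef)) {
          if (!is.null(wcoef[[w]])) {
            col <- prod_covariate_column[[w]]
            if (is.null(weather) || !col %in% names(weather)) {
              stop("weather column '", col, "' required by variant")
            }
            lq <- lq + wcoef[[w]][alive] * weather[[col]][t + 1]
          }
        }
        lam <- L[alive] * exp(pmin(pmax(lq, -700), 700))
        En[alive] <- if (demographic) stats::rpois(sum(alive), lam) else lam
      }
      E <- En
    }
  }
  extinct <- apply(cbind(eggs, larv) == 0, 1, any)
  bands <- do.call(rbind, lapply(seq_len(H), function(t) {
    do.call(rbind, lapply(c("eggs", "larvae"), function(stage) {
      x <- if (stage == "eggs") eggs[, t] else larv[, t]
      data.frame(year = t, stage = stage, mean = mean(x),
                 median = stats::median(x),
                 q25 = stats::quantile(x, 0.25, names = FALSE),
                 q75 = stats::quantile(x, 0.75, names = FALSE))
    }))
  }))
  structure(list(trajectories = list(eggs = eggs, larvae = larv),
                 extinct_fraction = mean(extinct),
                 quantile_bands = bands, horizon = H, n_reps = n_reps),
            class = "moth_sim")
}

#' @export
print.moth_sim <- function(x, ...) {
  cat("Stochastic trajectory simulation: ", x$n_reps, " replicates x ",
      x$horizon, " years\n", sep = "")
  cat("Extinct by final year: ", round(100 * x$extinct_fraction, 1),
      "% of replicates\n", sep = "")
  invisible(x)
}

#' Write simulated trajectories to CSV
#'
#' Long format: `replicate`, `year`, `eggs`, `larvae`.
#'
#' @param sim a `moth_sim`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_trajectories <- function(sim, path) {
  long <- expand.grid(replicate = seq_len(sim$n_reps),
                      year = seq_len(sim$horizon),
                      KEEP.OUT.ATTRS = FALSE)
  long$eggs <- as.vector(sim$trajectories$eggs)
  long$larvae <- as.vector(sim$trajectories$larvae)
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Posterior response curves for survival and per-capita production
#'
#' Expected egg-to-larva survival across a grid of development times or
#' egg densities (the other input held fixed), or expected per-capita egg
#' production across larval densities. For each posterior draw the year
#' effect is either integrated out by simulation (`marginal = TRUE`,
#' default) or set to zero; the median and central 50\% band are then
#' taken across posterior draws.
#'
#' @param fit a `moth_fit`.
#' @param vary `"dev_time"`, `"eggs"` (survival curves) or `"larvae"`
#'   (production curve).
#' @param fixed_value the held-fixed input: egg count when varying
#'   development time, development time (days) when varying eggs; unused
#'   for `"larvae"`.
#' @param grid grid of values for the varying input (must respect the log
#'   domain, i.e. positive).
#' @param marginal integrate over the year effect by simulation
#'   (`n_eff` draws per posterior draw) rather than setting it to zero.
#' @param n_draws posterior draws used.
#' @param n_eff Monte-Carlo draws of the year effect per posterior draw.
#' @param seed optional integer seed.
#' @return data.frame with the grid value, `median`, `q25`, `q75`, `mean`.
#' @export
response_curve <- function(fit, vary = c("dev_time", "eggs", "larvae"),
                           fixed_value = NULL, grid, marginal = TRUE,
                           n_draws = 500, n_eff = 100, seed = NULL) {
  vary <- match.arg(vary)
  if (!is.null(seed)) set.seed(seed)
  if (any(grid <= 0)) stop("grid values must be positive (log domain)")
  hp <- posterior_draws(fit, fit$hyper_names)
  idx <- if (nrow(hp) > n_draws) sample.int(nrow(hp), n_draws) else
    seq_len(nrow(hp))
  hp <- hp[idx, , drop = FALSE]
  nd <- nrow(hp)
  if (vary %in% c("dev_time", "eggs") && is.null(fixed_value)) {
    stop("fixed_value required (eggs when varying dev_time, dev_time when ",
         "varying eggs)")
  }
  Z <- if (marginal) matrix(stats::rnorm(nd * n_eff), nd, n_eff) else
    matrix(0, nd, 1)
  out <- lapply(grid, function(gv) {
    if (vary == "larvae") {
      lq <- hp[, "mu"] + hp[, "f"] * log(gv)
      vals <- rowMeans(exp(lq + Z * hp[, "sigma_eta"]))
    } else {
      E <- if (vary == "eggs") gv else fixed_value
      d <- if (vary == "dev_time") gv else fixed_value
      lp <- hp[, "a"] + hp[, "b"] * log(E)
      if (variant_uses_devtime(fit$config$variant)) {
        lp <- lp + hp[, "c"] * log(d)
      }
      vals <- rowMeans(exp(-exp(-(lp + Z * hp[, "sigma_eps"]))))
    }
    data.frame(value = gv, median = stats::median(vals),
               q25 = stats::quantile(vals, 0.25, names = FALSE),
               q75 = stats::quantile(vals, 0.75, names = FALSE),
               mean = mean(vals))
  })
  out <- do.call(rbind, out)
  names(out)[1] <- vary
  out
}

#' @rdname response_curve
#' @export
survival_response_curve <- function(fit, vary = c("dev_time", "eggs"),
                                    fixed_value, grid, ...) {
  response_curve(fit, match.arg(vary), fixed_value, grid, ...)
}
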
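#' Fit the two-stage population model by MCMC
#'
#' Samples the joint posterior of the egg-to-larva survival submodel and the
#' larva-to-egg productivity submodel (see [log_posterior()]) with an
#' adaptive random-walk Metropolis-within-Gibbs kernel (compiled). Fixed
#' effects and standard deviations are updated with scalar proposals whose
#' step sizes adapt during warmup toward 44\% acceptance; the per-year
#' random effects, conditionally independent given the hyper-parameters,
#' are updated with vectorised single-site proposals.
#'
#' @param data a `moth_data` object with at least 3 usable survival years
#'   and 3 consecutive-year transitions; variants needing weather
#'   covariates require a weather table covering the observation years.
#' @param config a [model_config]; the seed makes the whole fit
#'   reproducible.
#' @return An object of class `moth_fit` with elements `draws` (array
#'   kept-iterations x parameters x chains), `param_names`, `summary`
#'   (see [summary.moth_fit()]), `rhat` per parameter, `converged`
#'   (all R-hat below the threshold; a warning is issued otherwise,
#'   never silently), `accept` rates, `config`, and the packed `data`.
#' @examples
#' \donttest{
#' d <- fixture_small()
#' f <- fit(d, model_config(n_iterations = 20000, seed = 1))
#' summary(f)
#' }
#' @export
fit <- function(data, config = model_config()) {
  stopifnot(inherits(data, "moth_data"), inherits(config, "model_config"))
  dat <- pack_fit_data(data, config)
  check_design_rank(dat, config)
  pn <- param_names_for(dat, config)
  n_par <- length(pn)
  n_sfix <- length(surv_fixed_names(config$variant))
  n_pfix <- length(prod_fixed_names(config$variant))

  set.seed(config$seed)
  chains <- vector("list", config$n_chains)
  accept <- vector("list", config$n_chains)
  for (k in seq_len(config$n_chains)) {
    init <- init_theta(dat, config)
    res <- cpp_run_chain(dat, init, n_sfix, n_pfix,
                         config$n_iterations, config$n_warmup, config$thin)
    chains[[k]] <- res$draws
    accept[[k]] <- res$accept
  }
  n_kept <- nrow(chains[[1]])
  draws <- array(unlist(chains), dim = c(n_kept, n_par, config$n_chains),
                 dimnames = list(NULL, pn, NULL))
  rh <- apply(draws, 2, function(m) rhat(m, split = TRUE))
  converged <- all(rh < config$rhat_threshold)
  obj <- structure(
    list(draws = draws, param_names = pn,
         hyper_names = c(surv_fixed_names(config$variant), "sigma_eps",
                         prod_fixed_names(config$variant), "sigma_eta"),
         rhat = rh, converged = converged,
         accept = Reduce(`+`, accept) / length(accept),
         config = config, dat = dat, data = data),
    class = "moth_fit")
  obj$summary <- summary(obj)
  if (!converged) {
    warning("MCMC not converged: max split R-hat = ",
            format(max(rh), digits = 4), " (threshold ",
            config$rhat_threshold, "); inspect chains or run longer",
            call. = FALSE)
  }
  obj
}

# overdispersed but sane chain starting points
init_theta <- function(dat, config) {
  n_sfix <- length(surv_fixed_names(config$variant))
  n_pfix <- length(prod_fixed_names(config$variant))
  Ty <- length(dat$surv_years)
  Tr <- length(dat$trans_years)
  c(stats::rnorm(n_sfix, 0, 1), 0.2 + stats::rexp(1, 2),
    stats::rnorm(Ty, 0, 0.3),
    stats::rnorm(n_pfix, 0, 1), 0.2 + stats::rexp(1, 2),
    stats::rnorm(Tr, 0, 0.3))
}

# flag unidentifiable designs (e.g. constant eggs and development times)
check_design_rank <- function(dat, config) {
  X <- cbind(1, dat$logE)
  labs <- c("intercept", "log eggs")
  if (dat$use_d == 1) { X <- cbind(X, dat$logd); labs <- c(labs, "log dev time") }
  if (dat$use_temp == 1) { X <- cbind(X, dat$temp); labs <- c(labs, "summer temp") }
  if (qr(scale(X, center = FALSE, scale = FALSE))$rank < ncol(X)) {
    warning("survival design is rank-deficient (collinear or constant ",
            "columns among ", paste(labs, collapse = ", "),
            "); density-dependence and development-time slopes are not ",
            "identifiable and will have very wide intervals", call. = FALSE)
  }
  Xp <- cbind(1, dat$logLprev, dat$Xw)
  if (qr(Xp)$rank < ncol(Xp)) {
    warning("productivity design is rank-deficient; slopes are not ",
            "identifiable", call. = FALSE)
  }
  invisible(TRUE)
}

meaning_strings <- c(
  a = "Intercept for hazard rate",
  b = "Slope for density dependence",
  c = "Slope for development time",
  sigma_eps = "SD for random year effect",
  g_temp = "Slope for summer temp on larval survival",
  mu = "Intercept",
  f = "Slope for density dependence",
  sigma_eta = "SD for random year effect",
  w_winter_min = "Slope for winter min temp",
  w_snow = "Slope for days of snow cover",
  w_spring = "Slope for spring temperature")

#' Posterior summary table
#'
#' One row per hyper-parameter (per-year random effects are excluded by
#' default, matching the convention of reporting only the model's
#' structural parameters): point estimate (posterior mean), posterior
#' median, 95\% HPD interval, and split R-hat.
#'
#' @param object a `moth_fit`.
#' @param mass HPD interval mass (default 0.95).
#' @param random_effects include the per-year effects `eps[year]`,
#'   `eta[year]` as extra rows.
#' @param ... unused.
#' @return A data.frame with columns `parameter`, `meaning`, `estimate`,
#'   `median`, `hpd_lower`, `hpd_upper`, `rhat`.
#' @export
summary.moth_fit <- function(object, mass = 0.95, random_effects = FALSE,
                             ...) {
  keep <- if (random_effects) object$param_names else object$hyper_names
  rows <- lapply(keep, function(p) {
    x <- as.vector(object$draws[, p, ])
    h <- hpd_interval(x, mass)
    base <- sub("\\[.*", "", p)
    data.frame(parameter = p,
               meaning = if (base %in% names(meaning_strings))
                 meaning_strings[[base]] else "Random year effect",
               estimate = mean(x), median = stats::median(x),
               hpd_lower = h[["lower"]], hpd_upper = h[["upper"]],
               rhat = object$rhat[[p]])
  })
  do.call(rbind, rows)
}

#' @export
print.moth_fit <- function(x, digits = 3, ...) {
  cat("Two-stage insect population model fit (variant '",
      x$config$variant, "')\n", sep = "")
  cat(dim(x$draws)[3], " chains x ", x$config$n_iterations,
      " iterations (warmup ", x$config$n_warmup, ", thin ", x$config$thin,
      "); ", dim(x$draws)[1] * dim(x$draws)[3], " kept draws\n", sep = "")
  cat("Converged: ", x$converged, " (max split R-hat ",
      format(max(x$rhat), digits = 4), ")\n\n", sep = "")
  s <- x$summary
  s[c("estimate", "median", "hpd_lower", "hpd_upper", "rhat")] <-
    lapply(s[c("estimate", "median", "hpd_lower", "hpd_upper", "rhat")],
           round, digits)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Pooled posterior draws of the hyper-parameters
#'
#' @param fit a `moth_fit`.
#' @param params parameter names (default: all parameters, including
#'   per-year effects).
#' @return Matrix with one row per kept draw (all chains pooled) and one
#'   column per parameter.
#' @export
posterior_draws <- function(fit, params = fit$param_names) {
  out <- sapply(params, function(p) as.vector(fit$draws[, p, ]))
  if (is.null(dim(out))) out <- matrix(out, ncol = length(params),
                                       dimnames = list(NULL, params))
  out
}

#' Write posterior draws as a long CSV
#'
#' Columns `chain`, `iteration`, `parameter`, `value`, one row per kept
#' draw of each parameter.
#'
#' @param fit a `moth_fit`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_draws <- function(fit, path) {
  d <- fit$draws
  long <- expand.grid(iteration = seq_len(dim(d)[1]),
                      parameter = fit$param_names,
                      chain = seq_len(dim(d)[3]),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$value <- as.vector(d)
  utils::write.csv(long[c("chain", "iteration", "parameter", "value")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# draw rows of hyper-parameters as parameter objects, recycled as needed
draw_param_objects <- function(fit, indices) {
  dm <- posterior_draws(fit, fit$hyper_names)
  cfg <- fit$config
  lapply(indices, function(i) {
    row <- dm[i, ]
    sn <- surv_fixed_names(cfg$variant)
    pn <- prod_fixed_names(cfg$variant)
    surv <- survival_params(a = row[["a"]], b = row[["b"]],
                            c = if ("c" %in% sn) row[["c"]],
                            sigma_eps = row[["sigma_eps"]],
                            g_temp = if ("g_temp" %in% sn) row[["g_temp"]])
    prod <- productivity_params(mu = row[["mu"]], f = row[["f"]],
                                sigma_eta = row[["sigma_eta"]])
    for (w in variant_prod_covariates(cfg$variant)) prod[[w]] <- row[[w]]
    list(surv = surv, prod = prod)
  })
}
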
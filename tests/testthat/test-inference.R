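test_that("log prior matches closed-form densities and support bounds", {
  cfg <- model_config(seed = 1)  # B = 10, half-Cauchy scale 2.5
  sp <- survival_params(a = 1, b = -0.2, c = -1, sigma_eps = 0.3)
  pp <- productivity_params(mu = 2, f = -0.4, sigma_eta = 0.5)

  # 5 fixed effects in the base variant, each contributing ln(1/20)
  expected <- 5 * log(1 / 20) +
    (log(2) + stats::dcauchy(0.3, 0, 2.5, log = TRUE)) +
    (log(2) + stats::dcauchy(0.5, 0, 2.5, log = TRUE))
  expect_equal(log_prior(sp, pp, cfg), expected, tolerance = 1e-12)

  # half-Cauchy density at its scale is 1/(pi * scale)
  sp2 <- survival_params(a = 1, b = -0.2, c = -1, sigma_eps = 2.5)
  expect_equal(log_prior(sp2, pp, cfg) - log_prior(sp, pp, cfg),
               log(1 / (pi * 2.5)) -
                 (log(2) + stats::dcauchy(0.3, 0, 2.5, log = TRUE)),
               tolerance = 1e-12)

  # outside the uniform support
  sp3 <- survival_params(a = 10.1, b = -0.2, c = -1, sigma_eps = 0.3)
  expect_identical(log_prior(sp3, pp, cfg), -Inf)

  # random effects add their Normal log densities
  sp4 <- survival_params(a = 1, b = -0.2, c = -1, sigma_eps = 0.3,
                         eps = c(0.1, -0.2))
  expect_equal(log_prior(sp4, pp, cfg) - log_prior(sp, pp, cfg),
               sum(stats::dnorm(c(0.1, -0.2), 0, 0.3, log = TRUE)),
               tolerance = 1e-12)
})

test_that("log posterior is the sum of prior and both likelihoods", {
  cfg <- model_config(seed = 1)
  d <- tiny_data()
  sp <- survival_params(a = 3, b = -0.2, c = -1, sigma_eps = 0.3,
                        eps = rnorm(5, 0, 0.1))
  pp <- productivity_params(mu = 4, f = -0.4, sigma_eta = 0.5,
                            eta = rnorm(4, 0, 0.2))
  expect_equal(log_posterior(sp, pp, d, cfg),
               log_prior(sp, pp, cfg) + loglik_survival(sp, d) +
                 loglik_productivity(pp, d),
               tolerance = 1e-12)

  # too-small data errors rather than returning 0
  d1 <- moth_data(data.frame(year = 2000, eggs_laid = 10L, larvae_l5 = 2L,
                             dev_time_days = 40))
  expect_error(log_posterior(sp, pp, d1, cfg), "small|transition")

  # perturbing one year effect changes the posterior by that year's
  # binomial delta plus its Normal prior delta
  sp2 <- sp
  sp2$eps[3] <- sp$eps[3] + 0.17
  obs <- d$observations
  bin_term <- function(eps) {
    s <- survival_prob(sp, obs$eggs_laid[3], obs$dev_time_days[3],
                       eps_t = eps)
    stats::dbinom(obs$larvae_l5[3], obs$eggs_laid[3], s, log = TRUE)
  }
  delta <- bin_term(sp2$eps[3]) - bin_term(sp$eps[3]) +
    stats::dnorm(sp2$eps[3], 0, 0.3, log = TRUE) -
    stats::dnorm(sp$eps[3], 0, 0.3, log = TRUE)
  expect_equal(log_posterior(sp2, pp, d, cfg) - log_posterior(sp, pp, d, cfg),
               delta, tolerance = 1e-9)
})

test_that("compiled posterior agrees with the reference implementation", {
  cfg <- model_config(seed = 1)
  d <- tiny_data()
  dat <- mothwin:::pack_fit_data(d, cfg)
  set.seed(14)
  for (i in 1:20) {
    sp <- survival_params(a = rnorm(1, 2, 2), b = rnorm(1, 0, 0.5),
                          c = rnorm(1, -1, 0.5),
                          sigma_eps = runif(1, 0.05, 2),
                          eps = rnorm(5, 0, 0.5))
    pp <- productivity_params(mu = rnorm(1, 3, 2), f = rnorm(1, 0, 0.5),
                              sigma_eta = runif(1, 0.05, 2),
                              eta = rnorm(4, 0, 0.5))
    th <- mothwin:::pack_theta(sp, pp, dat, cfg)
    expect_equal(mothwin:::cpp_log_posterior(dat, th, 3L, 2L),
                 log_posterior(sp, pp, d, cfg), tolerance = 1e-10)
  }
})

test_that("exchanging two identical years leaves the posterior invariant", {
  obs <- data.frame(year = 2000:2004,
                    eggs_laid = c(200L, 120L, 120L, 300L, 250L),
                    larvae_l5 = c(20L, 11L, 11L, 30L, 25L),
                    dev_time_days = c(40, 45, 45, 38, 42))
  d <- moth_data(obs)
  cfg <- model_config(seed = 1)
  sp <- survival_params(a = 3, b = -0.2, c = -1, sigma_eps = 0.3,
                        eps = c(0.1, -0.3, 0.25, 0.05, -0.1))
  pp <- productivity_params(mu = 4, f = -0.4, sigma_eta = 0.5)
  base <- log_posterior(sp, pp, d, cfg)
  # years 2001 and 2002 are identical; swapping their effects is invariant
  sp_swapped <- sp
  sp_swapped$eps[2:3] <- sp$eps[3:2]
  expect_equal(log_posterior(sp_swapped, pp, d, cfg), base,
               tolerance = 1e-12)
})

test_that("split R-hat behaves at its analytic reference points", {
  set.seed(3)
  x <- rnorm(100)
  # exact-copy chains, classic form: sqrt((n-1)/n)
  expect_equal(rhat(cbind(x, x), split = FALSE), sqrt(99 / 100),
               tolerance = 1e-12)
  # stationary chains from the same Normal converge to 1
  draws <- matrix(rnorm(4 * 5000), ncol = 4)
  expect_lt(abs(rhat(draws) - 1), 0.01)
  # disjoint chains are flagged far above the 1.01 gate
  bad <- cbind(rnorm(500, 0, 1), rnorm(500, 10, 1))
  expect_gt(rhat(bad), 3)
  expect_error(rhat(matrix(rnorm(10), ncol = 1)), "2 chains")
})

test_that("HPD interval is the shortest window at the requested mass", {
  expect_equal(unname(hpd_interval(rep(2.5, 30))), c(2.5, 2.5))

  set.seed(10)
  z <- rnorm(100000)
  h <- hpd_interval(z, 0.95)
  expect_lt(abs(h[["lower"]] + 1.96), 0.05)
  expect_lt(abs(h[["upper"]] - 1.96), 0.05)

  # right-skewed sample: HPD beats the equal-tailed interval, and matches
  # a brute-force search over candidate windows
  x <- rexp(5000)
  h <- hpd_interval(x, 0.9)
  eq <- stats::quantile(x, c(0.05, 0.95), names = FALSE)
  expect_lt(h[["upper"]] - h[["lower"]], eq[2] - eq[1])
  xs <- sort(x)
  m <- ceiling(0.9 * length(xs))
  widths <- xs[m:length(xs)] - xs[1:(length(xs) - m + 1)]
  expect_equal(h[["upper"]] - h[["lower"]], min(widths), tolerance = 1e-12)

  expect_error(hpd_interval(rnorm(10)), "20 samples")
})

test_that("the sampler is deterministic under a fixed seed", {
  d <- fixture_small()
  cfg <- model_config(n_iterations = 3000, thin = 5, seed = 77)
  f1 <- suppressWarnings(fit(d, cfg))
  f2 <- suppressWarnings(fit(d, cfg))
  expect_identical(f1$draws, f2$draws)
})

test_that("posterior draws respect the prior support", {
  f <- fit_fixture()
  dm <- posterior_draws(f, f$hyper_names)
  B <- f$config$prior_fixed_bound
  for (p in c("a", "b", "c", "mu", "f")) {
    expect_true(all(abs(dm[, p]) < B))
  }
  expect_true(all(dm[, "sigma_eps"] > 0))
  expect_true(all(dm[, "sigma_eta"] > 0))
})

test_that("MCMC marginal moments match dense-grid integration on a reduced posterior", {
  # the joint posterior factorises over the two submodels, so the
  # productivity-block marginals can be computed by 3-D quadrature with
  # the per-transition year effects integrated out on a fine grid
  f <- grid_oracle_fit()
  oracle <- grid_oracle_moments()
  dm <- posterior_draws(f, c("mu", "f", "sigma_eta"))
  for (p in c("mu", "f", "sigma_eta")) {
    expect_lt(abs(mean(dm[, p]) - oracle[[p]][["mean"]]),
              0.06 + 0.05 * oracle[[p]][["sd"]])
    expect_lt(abs(sd(dm[, p]) - oracle[[p]][["sd"]]),
              0.1 * oracle[[p]][["sd"]] + 0.03)
  }
})

test_that("summary rows follow the model variant", {
  f <- fit_fixture()
  s <- summary(f)
  expect_equal(nrow(s), 7)
  expect_setequal(s$parameter, c("a", "b", "c", "sigma_eps", "mu", "f",
                                 "sigma_eta"))
  expect_equal(s$meaning[s$parameter == "a"], "Intercept for hazard rate")
  expect_equal(s$meaning[s$parameter == "c"], "Slope for development time")
  expect_true(all(s$hpd_lower <= s$estimate & s$estimate <= s$hpd_upper))

  sw <- summary(suppressWarnings(
    fit(fixture_small(), model_config("winter", n_iterations = 4000,
                                      seed = 2))))
  expect_equal(nrow(sw), 9)
  expect_true(all(c("w_winter_min", "w_snow") %in% sw$parameter))
  expect_equal(sw$meaning[sw$parameter == "w_snow"],
               "Slope for days of snow cover")

  ss <- summary(suppressWarnings(
    fit(fixture_small(), model_config("spring", n_iterations = 4000,
                                      seed = 2))))
  expect_equal(nrow(ss), 8)
  expect_true("w_spring" %in% ss$parameter)

  # random effects appear only on request
  expect_gt(nrow(summary(f, random_effects = TRUE)), 7)
})

test_that("degenerate constant designs trigger a collinearity warning", {
  d <- moth_data(data.frame(year = 2000:2005, eggs_laid = rep(100L, 6),
                            larvae_l5 = rep(10L, 6),
                            dev_time_days = rep(40, 6)))
  warns <- character()
  withCallingHandlers(
    fit(d, model_config(n_iterations = 2000, seed = 1)),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  expect_true(any(grepl("rank-deficient", warns)))
})

test_that("missing covariates for a variant are a clear error", {
  d <- fixture_small()
  d$weather <- NULL
  expect_error(fit(d, model_config("winter", n_iterations = 2000, seed = 1)),
               "weather")
})
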
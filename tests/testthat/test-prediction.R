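test_that("a point-mass posterior collapses one-step prediction onto E*s", {
  d <- tiny_data()
  surv <- survival_params(a = 3.8, b = -0.20, c = -1.0, sigma_eps = 1e-8)
  prod <- productivity_params(mu = 4.6, f = -0.41, sigma_eta = 1e-8)
  f <- fixed_fit(surv, prod, d)
  pred <- one_step_predict(f, mode = "L_from_E", n_draws = 2000, seed = 3)
  obs <- d$observations
  for (i in seq_len(nrow(pred))) {
    m <- obs$eggs_laid[i] *
      survival_prob(surv, obs$eggs_laid[i], obs$dev_time_days[i])
    sdev <- sqrt(m * (1 - m / obs$eggs_laid[i]))
    expect_lt(abs(pred$q50[i] - m), 3 * sdev)   # only binomial jitter left
  }
  expect_true(all(pred$q25 <= pred$q50 & pred$q50 <= pred$q75))
})

test_that("chained egg prediction equals productivity applied to predicted larvae", {
  f <- fit_fixture()
  d <- f$data
  set.seed(61)
  hp <- posterior_draws(f, f$hyper_names)
  idx <- sample.int(nrow(hp), 4000, replace = TRUE)
  hp <- hp[idx, ]
  obs <- d$observations
  t <- 4  # predict E in year t from E in year t-1
  # composition oracle: draw L via the survival model, then E via the
  # productivity model, independently of the implementation under test
  eps <- rnorm(4000, 0, hp[, "sigma_eps"])
  s <- exp(-exp(-(hp[, "a"] + hp[, "b"] * log(obs$eggs_laid[t - 1]) +
                    hp[, "c"] * log(obs$dev_time_days[t - 1]) + eps)))
  Lstar <- rbinom(4000, obs$eggs_laid[t - 1], s)
  alive <- Lstar >= 1
  Estar <- integer(4000)
  eta <- rnorm(sum(alive), 0, hp[alive, "sigma_eta"])
  Estar[alive] <- rpois(sum(alive), Lstar[alive] *
                          exp(hp[alive, "mu"] +
                                hp[alive, "f"] * log(Lstar[alive]) + eta))
  pred <- one_step_predict(f, mode = "E_from_E", n_draws = 4000, seed = 62,
                           return_draws = TRUE)
  impl <- attr(pred, "draws")[[as.character(obs$year[t])]]
  ks <- suppressWarnings(stats::ks.test(impl, Estar))
  expect_gt(ks$p.value, 0.01)
})

test_that("posterior predictive p-values behave at their reference points", {
  f <- fit_fixture()
  tab <- posterior_predictive_pvalues(f, n_rep = 400, seed = 9)
  expect_equal(nrow(tab), 8)
  expect_setequal(unique(tab$stage), c("eggs", "larvae"))
  expect_setequal(unique(tab$statistic), c("mean", "sd", "min", "max"))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  # the model fitted to its own data should not be flagged for misfit
  expect_true(mean(tab$pass) >= 0.75)

  # an impossible observed maximum drives p to 0 and raises the flag
  d2 <- f$data
  d2$observations$eggs_laid[8] <- 2000000L
  d2$observations$eggs_hatched[8] <- NA_integer_
  tab2 <- posterior_predictive_pvalues(f, data = d2, n_rep = 200, seed = 9)
  pmax_row <- tab2[tab2$stage == "eggs" & tab2$statistic == "max", ]
  expect_equal(pmax_row$p_value, 0)
  expect_false(pmax_row$pass)
})

test_that("trajectory simulation is absorbing, reproducible and band-monotone", {
  surv <- survival_params(a = 3.8, b = -0.20, c = -1.0, sigma_eps = 0.16)
  prod <- productivity_params(mu = 4.6, f = -0.41, sigma_eta = 0.49)
  pars <- list(surv = surv, prod = prod)

  # an empty start stays empty in every replicate
  sim0 <- simulate_trajectories(pars, initial_eggs = 0,
                                dev_times = rep(42, 10), n_reps = 50,
                                seed = 1)
  expect_true(all(sim0$trajectories$eggs == 0))
  expect_true(all(sim0$trajectories$larvae == 0))
  expect_equal(sim0$extinct_fraction, 1)

  sim <- simulate_trajectories(pars, initial_eggs = 374,
                               dev_times = rep(42, 15), n_reps = 400,
                               seed = 2)
  sim_b <- simulate_trajectories(pars, initial_eggs = 374,
                                 dev_times = rep(42, 15), n_reps = 400,
                                 seed = 2)
  expect_identical(sim$trajectories, sim_b$trajectories)

  # extinction is absorbing within every replicate, stage by stage
  for (r in seq_len(sim$n_reps)) {
    stages <- as.vector(rbind(sim$trajectories$eggs[r, ],
                              sim$trajectories$larvae[r, ]))
    hit <- which(stages == 0)
    if (length(hit) > 0) {
      expect_true(all(stages[hit[1]:length(stages)] == 0))
    }
  }
  b <- sim$quantile_bands
  expect_true(all(b$q25 <= b$median & b$median <= b$q75))
  expect_true(all(b$mean >= 0))
})

test_that("neutral dynamics hold the median trajectory at its start", {
  # survival forced to ~1 and per-capita rate to 1, no year effects:
  # only demographic jitter remains around the initial value
  surv <- survival_params(a = 50, b = 0, c = 0, sigma_eps = 1e-9)
  prod <- productivity_params(mu = 0, f = 0, sigma_eta = 1e-9)
  sim <- simulate_trajectories(list(surv = surv, prod = prod),
                               initial_eggs = 1000,
                               dev_times = rep(42, 8), n_reps = 400,
                               seed = 5)
  med <- sim$quantile_bands$median[sim$quantile_bands$stage == "eggs"]
  expect_true(all(abs(med - 1000) < 5 * sqrt(1000)))
})

test_that("disabling stochasticity reproduces the deterministic map", {
  surv <- survival_params(a = 3.8, b = -0.20, c = -1.0, sigma_eps = 0.16)
  prod <- productivity_params(mu = 4.6, f = -0.41, sigma_eta = 0.49)
  sim <- simulate_trajectories(list(surv = surv, prod = prod),
                               initial_eggs = 374,
                               dev_times = rep(42, 6), n_reps = 3,
                               seed = 1, demographic = FALSE,
                               environmental = FALSE)
  E <- 374
  for (t in 1:6) {
    s <- survival_prob(surv, E, 42)
    L <- E * s
    expect_equal(sim$trajectories$eggs[1, t], E, tolerance = 1e-9)
    expect_equal(sim$trajectories$larvae[1, t], L, tolerance = 1e-9)
    E <- L * exp(prod$mu + prod$f * log(L))
  }
})

test_that("response curves inherit monotonicity and collapse without uncertainty", {
  d <- tiny_data()
  surv <- survival_params(a = 3.8, b = -0.20, c = -1.0, sigma_eps = 1e-9)
  prod <- productivity_params(mu = 4.6, f = -0.41, sigma_eta = 1e-9)
  f0 <- fixed_fit(surv, prod, d)
  grid <- seq(30, 65, by = 5)
  rc <- response_curve(f0, "dev_time", fixed_value = 374, grid = grid,
                       n_draws = 100, seed = 3)
  # zero posterior and year-effect variance: band collapses onto the curve
  expect_equal(rc$q25, rc$q75, tolerance = 1e-9)
  expect_equal(rc$median,
               vapply(grid, function(g) survival_prob(surv, 374, g), 0),
               tolerance = 1e-6)
  expect_true(all(diff(rc$median) < 0))

  fr <- fit_fixture()
  rc2 <- response_curve(fr, "dev_time", fixed_value = 374, grid = grid,
                        n_draws = 300, n_eff = 50, seed = 4)
  expect_true(all(rc2$q25 <= rc2$median & rc2$median <= rc2$q75))
  expect_true(all(diff(rc2$median) < 0))
  # per-capita production curve declines in larval density
  rcL <- response_curve(fr, "larvae", grid = c(5, 20, 50, 150),
                        n_draws = 300, n_eff = 50, seed = 5)
  expect_true(all(diff(rcL$median) < 0))

  expect_error(response_curve(fr, "dev_time", fixed_value = 374,
                              grid = c(-5, 10)), "positive")
})
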
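test_that("cloglog survival matches direct formula evaluation", {
  # zero linear predictor forces s = exp(-1)
  p0 <- survival_params(a = 0, b = 0, c = 0, sigma_eps = 1)
  expect_equal(survival_prob(p0, eggs = 1, dev_time = 1), exp(-1))

  # reference parameters at the median egg count and development time
  p <- survival_params(a = 3.8, b = -0.20, c = -1.0, sigma_eps = 0.16)
  s42 <- exp(-exp(-(3.8 - 0.20 * log(374) - 1.0 * log(42))))
  expect_equal(survival_prob(p, 374, 42), s42, tolerance = 1e-12)
  expect_equal(round(survival_prob(p, 374, 42), 4), 0.0463)

  # a longer window of vulnerability lowers survival
  s60 <- survival_prob(p, 374, 60)
  expect_equal(round(s60, 4), 0.0124)
  expect_lt(s60, s42)

  # domain errors: log undefined
  expect_error(survival_prob(p, eggs = 0, dev_time = 42), "eggs")
  expect_error(survival_prob(p, eggs = 374, dev_time = 0), "dev_time")
})

test_that("survival is monotone in the linear predictor and its drivers", {
  p <- survival_params(a = 3.8, b = -0.20, c = -1.0, sigma_eps = 0.16)
  d_grid <- seq(25, 80, by = 5)
  s_d <- survival_prob(p, 374, d_grid)
  expect_true(all(diff(s_d) < 0))        # c < 0: decreasing in dev time
  e_grid <- c(50, 100, 200, 400, 800)
  s_e <- survival_prob(p, e_grid, 42)
  expect_true(all(diff(s_e) < 0))        # b < 0: decreasing in density
  eps_grid <- seq(-1, 1, by = 0.25)
  s_eps <- survival_prob(p, 374, 42, eps_t = eps_grid)
  expect_true(all(diff(s_eps) > 0))      # increasing in the predictor
})

test_that("the link is survival under a Weibull hazard with shape -c", {
  expect_equal(hazard_shape(survival_params(a = 1, b = 0, c = -1.0,
                                            sigma_eps = 1)), 1.0)
  expect_equal(hazard_shape(survival_params(a = 1, b = 0, c = 0,
                                            sigma_eps = 1)), 0)
  expect_equal(hazard_shape(-2), 2)

  # -ln s(d) = lambda * d^(-c) with lambda = exp(-(a + b ln E + eps))
  grid <- expand.grid(a = c(1, 3.8), b = c(-0.2, 0), c = c(-2, -1, -0.5),
                      E = c(50, 374), d = c(10, 42, 60), eps = c(-0.3, 0.2))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    p <- survival_params(a = g$a, b = g$b, c = g$c, sigma_eps = 1)
    lambda <- exp(-(g$a + g$b * log(g$E) + g$eps))
    hazard <- lambda * g$d^(-g$c)
    if (hazard > 500) next  # survival underflows a double
    expect_equal(-log(survival_prob(p, g$E, g$d, eps_t = g$eps)),
                 hazard, tolerance = 1e-10)
  }

  # shape 1 (c = -1) is a constant hazard: memoryless composition
  p1 <- survival_params(a = 3.8, b = -0.2, c = -1, sigma_eps = 1)
  for (dd in list(c(10, 20), c(5, 37), c(21, 21))) {
    expect_equal(survival_prob(p1, 374, sum(dd)),
                 survival_prob(p1, 374, dd[1]) *
                   survival_prob(p1, 374, dd[2]),
                 tolerance = 1e-12)
  }
})

test_that("binomial log-likelihood matches the pmf oracle", {
  # s forced to 0.5 via a = -log(log 2), all slopes zero
  p <- survival_params(a = -log(log(2)), b = 0, c = 0, sigma_eps = 1)
  d1 <- moth_data(data.frame(year = 2000, eggs_laid = 10L, larvae_l5 = 3L,
                             dev_time_days = 40))
  expect_equal(survival_prob(p, 10, 40), 0.5, tolerance = 1e-12)
  expect_equal(loglik_survival(p, d1), log(choose(10, 3) * 0.5^10),
               tolerance = 1e-10)

  # certainty limit: L = E with s -> 1 gives log-likelihood -> 0 from below
  phigh <- survival_params(a = 30, b = 0, c = 0, sigma_eps = 1)
  dall <- moth_data(data.frame(year = 2000, eggs_laid = 10L,
                               larvae_l5 = 10L, dev_time_days = 40))
  ll <- loglik_survival(phigh, dall)
  expect_lt(ll, 0)
  expect_gt(ll, -1e-10)

  # additivity: two identical years give exactly twice the value
  d2 <- moth_data(data.frame(year = 2000:2001, eggs_laid = c(10L, 10L),
                             larvae_l5 = c(3L, 3L),
                             dev_time_days = c(40, 40)))
  expect_equal(loglik_survival(p, d2), 2 * loglik_survival(p, d1))

  # fitting preconditions
  dz <- moth_data(data.frame(year = 2000:2001, eggs_laid = c(0L, 10L),
                             larvae_l5 = c(0L, 3L),
                             dev_time_days = c(40, 40)))
  expect_error(loglik_survival(p, dz), "exclude")
})

test_that("binomial simulation is reproducible and matches its moments", {
  p <- survival_params(a = 3.8, b = -0.2, c = -1, sigma_eps = 0.16)
  expect_identical(simulate_larvae(p, 374, 42, seed = 7),
                   simulate_larvae(p, 374, 42, seed = 7))

  # s forced to the boundaries
  p1 <- survival_params(a = 1000, b = 0, c = 0, sigma_eps = 1)
  expect_equal(simulate_larvae(p1, 50, 40, seed = 1), 50)
  p0 <- survival_params(a = -1000, b = 0, c = 0, sigma_eps = 1)
  expect_equal(simulate_larvae(p0, 50, 40, seed = 1), 0)

  # Monte-Carlo mean within 3 SE of the binomial expectation
  ps <- survival_params(a = -log(log(1 / 0.1)), b = 0, c = 0, sigma_eps = 1)
  expect_equal(survival_prob(ps, 1000, 40), 0.1, tolerance = 1e-12)
  set.seed(99)
  L <- simulate_larvae(ps, rep(1000, 10000), 40)
  se <- sqrt(1000 * 0.1 * 0.9 / 10000)
  expect_lt(abs(mean(L) - 100), 3 * se)
})

test_that("simulated survival with drawn year effects matches the marginal expectation", {
  p <- survival_params(a = 3.8, b = -0.2, c = -1, sigma_eps = 0.3)
  # eps-integrated survival by quadrature
  marg <- stats::integrate(function(e) {
    vapply(e, function(ei) survival_prob(p, 374, 42, eps_t = ei), 0) *
      stats::dnorm(e, 0, p$sigma_eps)
  }, -3, 3)$value
  set.seed(4)
  n <- 40000
  L <- simulate_larvae(p, rep(374, n), 42, eps_t = "draw")
  phat <- mean(L) / 374
  se <- stats::sd(L / 374) / sqrt(n)
  expect_lt(abs(phat - marg), 4 * se)
})
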
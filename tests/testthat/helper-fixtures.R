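# Shared fixtures and small oracles. Expensive objects (MCMC fits) are
# built once per test run and cached.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache)
}

table1_truth <- c(a = 3.8, b = -0.20, c = -1.0, sigma_eps = 0.16,
                  mu = 4.6, f = -0.41, sigma_eta = 0.49)

# minimal hand-built dataset: 5 years, valid for both submodels
tiny_data <- function() {
  moth_data(data.frame(
    year = 2000:2004,
    eggs_laid = c(200L, 150L, 300L, 250L, 180L),
    larvae_l5 = c(20L, 15L, 30L, 25L, 18L),
    dev_time_days = c(40, 45, 38, 42, 44)))
}

# dataset driving the grid-integration oracle: larval counts spread widely
# so the productivity block posterior is tight enough for a modest grid
grid_oracle_data <- function() {
  E <- c(60L, 52L, 142L, 547L, 42L, 273L, 63L, 295L, 87L)
  L <- c(3L, 30L, 120L, 5L, 35L, 8L, 50L, 12L, 40L)
  moth_data(data.frame(year = 2000:2008, eggs_laid = E, larvae_l5 = L,
                       dev_time_days = c(40, 55, 35, 50, 38, 60, 42, 52,
                                         45)))
}

# a moth_fit whose posterior is a point mass at the given parameters,
# for degenerate-limit checks of the prediction machinery
fixed_fit <- function(surv, prod, data, variant = "base", n_kept = 200) {
  cfg <- model_config(variant = variant)
  hyper <- c(mothwin:::surv_fixed_names(variant), "sigma_eps",
             mothwin:::prod_fixed_names(variant), "sigma_eta")
  vals <- c(a = surv$a, b = surv$b, c = surv$c, g_temp = surv$g_temp,
            sigma_eps = surv$sigma_eps, mu = prod$mu, f = prod$f,
            w_winter_min = prod$w_winter_min, w_snow = prod$w_snow,
            w_spring = prod$w_spring, sigma_eta = prod$sigma_eta)
  draws <- array(rep(vals[hyper], each = n_kept),
                 dim = c(n_kept, length(hyper), 2),
                 dimnames = list(NULL, hyper, NULL))
  structure(list(draws = draws, param_names = hyper, hyper_names = hyper,
                 rhat = stats::setNames(rep(1, length(hyper)), hyper),
                 converged = TRUE, config = cfg, data = data),
            class = "moth_fit")
}

fit_fixture <- function() {
  memo("fit_fixture", suppressWarnings(
    fit(fixture_small(), model_config(n_iterations = 100000, seed = 42))))
}

# long synthetic series at the reference truth, plus its fit
gen_T100 <- function() {
  memo("gen_T100", generate_dataset(generator_config(n_years = 100,
                                                     seed = 101)))
}

fit_T100 <- function() {
  memo("fit_T100", suppressWarnings(
    fit(gen_T100()$data, model_config(n_iterations = 40000, seed = 11))))
}

# independent log-likelihood oracles built on stats d* functions
oracle_loglik_survival <- function(params, data) {
  obs <- data$observations
  eps <- params$eps
  if (is.null(eps)) eps <- rep(0, nrow(obs))
  s <- vapply(seq_len(nrow(obs)), function(i) {
    survival_prob(params, obs$eggs_laid[i], obs$dev_time_days[i],
                  eps_t = eps[i])
  }, 0)
  sum(stats::dbinom(obs$larvae_l5, obs$eggs_laid, s, log = TRUE))
}

oracle_loglik_productivity <- function(params, data) {
  obs <- data$observations
  n <- nrow(obs)
  eta <- params$eta
  if (is.null(eta)) eta <- rep(0, n - 1)
  sum(vapply(2:n, function(t) {
    L <- obs$larvae_l5[t - 1]
    lam <- L * exp(params$mu + params$f * log(L) + eta[t - 1])
    stats::dpois(obs$eggs_laid[t], lam, log = TRUE)
  }, 0))
}

# random small dataset + parameters for the oracle comparisons; parameter
# ranges keep survival away from double underflow so both routes stay finite
random_case <- function() {
  n <- sample(3:7, 1)
  E <- sample(20:500, n, replace = TRUE)
  L <- rbinom(n, E, runif(1, 0.02, 0.5))
  L <- pmax(L, 1L)
  d <- data.frame(year = 2000 + seq_len(n) - 1, eggs_laid = E,
                  larvae_l5 = L,
                  dev_time_days = runif(n, 25, 60))
  list(data = moth_data(d),
       surv = survival_params(a = runif(1, 3, 5), b = runif(1, -0.3, 0.1),
                              c = runif(1, -1.2, -0.2),
                              sigma_eps = runif(1, 0.05, 0.5),
                              eps = rnorm(n, 0, 0.2)),
       prod = productivity_params(mu = runif(1, 2, 5),
                                  f = runif(1, -0.8, 0),
                                  sigma_eta = runif(1, 0.1, 0.8),
                                  eta = rnorm(n - 1, 0, 0.4)))
}

# dense-grid posterior moments of (mu, f, sigma_eta) for the productivity
# block, which the joint posterior factorises onto: the per-transition year
# effects are integrated out numerically on a fine grid
grid_moments_productivity <- function(data, mu_grid, f_grid, sig_grid,
                                      u_grid, scale = 2.5) {
  tr <- mothwin:::transition_frame(data)
  logL <- log(tr$larvae_prev)
  Eobs <- tr$eggs
  du <- u_grid[2] - u_grid[1]
  nmf <- length(mu_grid) * length(f_grid)
  mu_v <- rep(mu_grid, times = length(f_grid))
  f_v <- rep(f_grid, each = length(mu_grid))
  logpost <- matrix(0, nmf, length(sig_grid))
  for (si in seq_along(sig_grid)) {
    sig <- sig_grid[si]
    lp <- rep(log(2) + stats::dcauchy(sig, 0, scale, log = TRUE), nmf)
    wu <- stats::dnorm(u_grid, 0, sig, log = TRUE) + log(du)
    for (i in seq_along(Eobs)) {
      A <- logL[i] + mu_v + f_v * logL[i]          # log lambda at u = 0
      M <- outer(A, u_grid, "+")                   # log lambda grid
      M <- Eobs[i] * M - exp(M)
      M <- sweep(M, 2, wu, "+")
      mx <- apply(M, 1, max)
      lp <- lp + mx + log(rowSums(exp(M - mx)))    # log-sum-exp over u
    }
    logpost[, si] <- lp
  }
  w <- exp(logpost - max(logpost))
  # the grid must contain essentially all posterior mass: edge densities
  # below ~2e-4 of the peak shift the moments far below the comparison
  # tolerance. The lower sigma edge is exempt: it approximates the sigma = 0
  # support boundary, where nonzero density is legitimate and the truncated
  # sliver [0, sig_grid[1]] carries negligible mass.
  edge <- max(w[c(1:length(mu_grid), nmf - length(mu_grid) + 1:length(mu_grid)), ],
              w[, ncol(w)],
              w[seq(1, nmf, by = length(mu_grid)), ],
              w[seq(length(mu_grid), nmf, by = length(mu_grid)), ])
  stopifnot(edge < 2e-4, sig_grid[1] < 0.01)
  w <- w / sum(w)
  wm <- rowSums(w)
  moment <- function(x, wts) {
    m <- sum(x * wts)
    c(mean = m, sd = sqrt(sum((x - m)^2 * wts)))
  }
  list(mu = moment(mu_v, wm), f = moment(f_v, wm),
       sigma_eta = moment(sig_grid, colSums(w)))
}

# canonical oracle fit + grid moments, shared across test files
grid_oracle_fit <- function() {
  memo("fit_grid_oracle", suppressWarnings(
    fit(grid_oracle_data(), model_config(n_iterations = 120000, seed = 5))))
}

grid_oracle_moments <- function() {
  memo("grid_oracle_moments", grid_moments_productivity(
    grid_oracle_data(),
    mu_grid = seq(1.2, 4.8, by = 0.05),
    f_grid = seq(-0.9, 0.35, by = 0.025),
    sig_grid = seq(0.005, 2.2, by = 0.025),
    u_grid = seq(-5, 5, by = 0.05)))
}
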
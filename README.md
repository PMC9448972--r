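# mothwin

Hierarchical Bayesian modelling of annual insect population dynamics for
univoltine species censused at two life-cycle stages per year: eggs laid
(E) and last-instar larvae (L). The package is aimed at population
ecologists analysing long annual census series of low-density insect
populations, where the questions are how much of the year-to-year change
is driven by weather, how much by density dependence, and how much
remains unexplained environmental or demographic noise.

## The model

The year is split into two stages.

**Egg → larva (summer).** Survival over the egg–larval development
window is binomial with a complementary log–log link:

```
L_t ~ Binomial(E_t, s_t)
s_t = exp(-exp(-(a + b·ln E_t + c·ln d_t + ε_t))),   ε_t ~ N(0, σ_ε)
```

where `d_t` is the development time in days (first observed egg to first
observed last-instar larva). This link makes `s_t` the survival
probability to time `d_t` under a Weibull hazard with shape `-c`:
`c = -1` is a constant per-day mortality hazard, so cool summers that
stretch the development window (the "window of vulnerability" to
generalist enemies) lower survival in proportion to the extra days of
exposure. `b` measures density dependence of survival.

**Larva → next year's eggs (autumn–winter–spring).** The lumped
pupal–adult–oviposition step is Poisson with log-linear per-capita
productivity:

```
E_t ~ Poisson(L_{t-1} · exp(μ + f·ln L_{t-1} + η_t)),   η_t ~ N(0, σ_η)
```

Optional weather covariates (winter minimum temperature plus snow-day
duration, spring temperature, or a direct summer-temperature effect on
survival) define the model variants. Fitting is by adaptive
Metropolis-within-Gibbs MCMC (compiled), with vague uniform priors on
fixed effects, half-Cauchy priors on the random-effect SDs, split-chain
R-hat convergence gating at 1.01, and 95% highest-posterior-density
summaries. Prediction, posterior predictive checking, response curves,
and stochastic multi-year simulation with absorbing extinction are
built in, as is a synthetic-data generator for simulation studies and a
phenology module (development-time construction and its
temperature regression). See the vignette
(`vignettes/moth-population-dynamics.Rmd`) for the full methods account.

## Worked example

Fit the base model to the packaged 15-year synthetic dataset (generated
at the package's reference parameter values; also shipped as CSV under
`inst/extdata/`):

```r
library(mothwin)
d <- fixture_small()
d
#> Annual insect census dataset (15 years: 1990-2004)
#>   eggs laid   : 70-972
#>   L5 larvae   : 1-66
#>   dev time (d): 29-51
#>   weather     : present; counts pooled over patches

f <- fit(d, model_config(seed = 1))
f
#> Two-stage insect population model fit (variant 'base')
#> 4 chains x 100000 iterations (warmup 50000, thin 10); 20000 kept draws
#> Converged: TRUE (max split R-hat 1.004)
#>
#>  parameter                      meaning estimate median hpd_lower hpd_upper
#>          a    Intercept for hazard rate    3.486  3.507     0.672     6.375
#>          b Slope for density dependence   -0.175 -0.173    -0.340    -0.019
#>          c   Slope for development time   -0.953 -0.959    -1.622    -0.289
#>  sigma_eps    SD for random year effect    0.230  0.219     0.116     0.358
#>         mu                    Intercept    4.155  4.158     3.297     5.008
#>          f Slope for density dependence   -0.356 -0.357    -0.649    -0.071
#>  sigma_eta    SD for random year effect    0.620  0.593     0.380     0.924
```

Both density-dependence slopes come out negative (survival falls with
egg density, per-capita productivity falls with larval density) and the
development-time slope sits near −1 — a constant per-day mortality
hazard, so each extra day of development costs a roughly constant
fraction of the cohort. The intervals cover the generator's true values
(a = 3.8, b = −0.20, c = −1.0, σ_ε = 0.16, μ = 4.6, f = −0.41,
σ_η = 0.49).

Posterior predictive checks and forward simulation:

```r
posterior_predictive_pvalues(f, n_rep = 500, seed = 3)
#>   stage statistic  observed p_value pass
#>    eggs      mean 510.85714   0.418 TRUE
#>    eggs        sd 320.30655   0.584 TRUE
#>    eggs       min  70.00000   0.458 TRUE
#>    eggs       max 972.00000   0.688 TRUE
#>  larvae      mean  24.13333   0.396 TRUE
#>  larvae        sd  19.97451   0.474 TRUE
#>  larvae       min   1.00000   0.704 TRUE
#>  larvae       max  66.00000   0.514 TRUE

sim <- simulate_trajectories(f, initial_eggs = 374,
                             dev_times = d$observations$dev_time_days,
                             n_reps = 1000, seed = 2)
sim
#> Stochastic trajectory simulation: 1000 replicates x 15 years
#> Extinct by final year: 24.3% of replicates
```

All eight predictive p-values sit inside the (0.05, 0.95) band — no
evidence of misfit — and simulating the fitted model forward for 15
years shows a substantial local extinction risk (about a quarter of
replicates), a hallmark of small populations with this much unexplained
winter-period variation.

A command-line front end over the same functions ships in
`inst/cli/mothwin` (subcommands `synth`, `fit`, `summarize`, `predict`,
`ppc`, `simulate`, `phenology`; see `?run_cli`).

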
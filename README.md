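# pancycle

Bayesian hierarchical panel autoregressions with unknown order, for
population-cycle analysis of ecological monitoring data.

## The problem

Rodent monitoring programmes yield *panels* of short annual time series:
yearly standardized captures at tens of locations over ~30 years.  The
population biology lives in the autoregressive structure of the yearly
growth rate — how many years of delayed density dependence act (the AR
order *p*), and what quasi-cycles the fitted coefficients imply.  Single
series of that length cannot identify an AR(3) or AR(4) reliably;
`pancycle` pools a homogeneous subgroup of locations in one mixed-effects
AR model and treats the order itself as unknown.

For location *k* and year *t*, the growth rate
`Y[k,t] = (Z[k,t] − Z[k,t−1]) / (1 + Z[k,t−1])` (with `Z` the density)
follows

    Y[k,t] = theta0[k] + sum_{j=1..p} theta_j[k] * Y[k,t−j] + eta[t] + e[k,t]

with location coefficients `theta[k] ~ N(mu, xi I)` shrunk to a common
mean, a shared yearly effect `eta[t] ~ N(0, sigma2_eta)` inducing spatial
synchrony, errors `e[k,t] ~ N(0, 1/tau[k])` with a log-normal variance
hierarchy `log(1/tau[k]) = log(1/tau) + N(0, sigma2_tau)`, and the
factorial prior `p(p) ∝ 1/(p+1)!` over orders `1..p_max`.  The AR order is
sampled by reversible-jump MCMC: the coefficient block `(mu, theta)` is
integrated out analytically, so trans-order moves are judged on the exact
marginal order posterior.  Fitted coefficients are turned into cycle
lengths through the characteristic roots: each complex pair `r·e^{±iω}`
is a damped quasi-cycle of period `2π/ω` years.

The package also ships the workflow around the model: trap-count
preprocessing (protocol-standardized densities, growth rates, species
dominance), correlation-based Ward clustering of series into homogeneous
subgroups with a dendrogram-cut heuristic, Geweke convergence diagnostics,
temperature summaries (Kira's warmth index, winter/summer means), a
synthetic-data generator that draws from the exact model, and
simulation-study machinery (order recovery, coverage).

## Worked example

Simulate a reference panel — 12 locations, 31 years, AR(2) dynamics with a
3.3-year quasi-cycle of damping 0.8 — and fit it with order unknown up to
`p_max = 4`:

```r
library(pancycle)

panel <- simulate_panel(m = 12, n = 31, seed = 11)
fit <- pan_ar(panel, p_max = 4,
              control = pan_control(iterations = 4000, burn_in = 1000,
                                    thinning = 3), seed = 2)
summary(fit)
#> Posterior summary (1000 retained draws)
#> AR order posterior: P(1)=0.000  P(2)=0.995  P(3)=0.005  P(4)=0.000
#> Modal order: 2  (coefficient block conditional on it, 995 draws)
#>
#>   parameter     mean      sd    lower  upper geweke_z
#>         mu0 -0.01352 0.06227 -0.12942  0.111   -0.910
#>         mu1 -0.58345 0.04821 -0.67541 -0.491    0.022
#>         mu2 -0.66156 0.04806 -0.75510 -0.567    2.299
#>         tau  4.70143 0.78293  3.40429  6.426    1.511
#>  sigma2_tau  0.23977 0.18635  0.02876  0.729    0.341
#>  sigma2_eta  0.07057 0.02669  0.03313  0.135   -1.070
#>          xi  0.00639 0.00328  0.00233  0.014    0.284
```

The sampler puts essentially all posterior mass on the generating order 2,
and the fixed effects recover the generating values
(`mu = (0, −0.523, −0.640)`) within their credible intervals; `geweke_z`
is an early-vs-late mean comparison that should look standard normal for a
converged chain.  The implied population cycle:

```r
cycle_lengths(fit)
#> AR(2) characteristic-root report (stationary)
#>  component modulus period_years root_re root_im
#>      cycle   0.813         3.24  -0.292   0.759
```

a damped quasi-cycle of 3.24 years (truth: 3.3 years, damping 0.8).
`coef()`, `fitted()`, `residuals()`, `plot()` and `simulate()` behave as
for any fitted-model object; `cycle_lengths(fit, posterior = TRUE)`
propagates coefficient uncertainty into the period.

Preprocessing and clustering mirror the field workflow:

```r
records <- read_captures("captures.csv")        # location,year,captures,trap_nights
dens    <- standardize_density(records)         # per 150 trap-nights
growth  <- panel_growth(dens)                   # adds growth_rate, respects gaps
subgr   <- cut_subgroups(ward_cluster(growth_dissimilarity(growth)))
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/pancycle.R` with subcommands `simulate`, `preprocess`,
`cluster`, `fit`, `summarize`, `cycles` and `study`; every run writes a
JSON manifest beside its output.

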
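# rwmscale

Dimension-dependent tuning of random walk Metropolis (RWM) algorithms from
Bayesian large-sample asymptotics.

## The problem

RWM proposes `theta' = theta + S %*% eps` with standard Gaussian `eps` and
accepts with probability `min(1, pi(theta') / pi(theta))`. The classical
guideline — scale the proposal so the acceptance rate is about 0.234 — comes
from high-dimensional limits of product-form targets, which real posteriors
rarely are. For a posterior built from *n* observations of a regular model,
however, a Bernstein–von Mises theorem makes the target approximately
Gaussian with covariance `I(theta0)^-1 / n` (inverse Fisher information), and
the standardized RWM chain converges, as `n` grows with the dimension `d`
fixed, to RWM on that Gaussian. The limiting chain can be analysed exactly,
yielding tuning rules that depend on `d` and account for parameter
correlation — usable on the very first run, with the observed information
standing in for the unknown Fisher information.

This package is for statisticians studying MCMC tuning and for
practitioners who want principled first-run proposal scalings for regular
Bayesian models.

## What it computes

With `lambda = ell / sqrt(d)` and a proposal matrix `M`:

* matched proposal (`M %*% t(M) = solve(I)`, "cholesky" mode): expected
  acceptance `2 E[pnorm(-(ell / (2 sqrt(d))) * chi_d)]` and metric ESJD
  (expected squared jumping distance)
  `2 lambda^2 E[chi_d^2 * pnorm(-(lambda / 2) * chi_d)]` — free of `I`,
  evaluated by quadrature or Monte Carlo (`acceptance_matched()`,
  `esjd_matched()`);
* isotropic proposal (`M = 1`, "identity" mode): the same forms with the
  metric norm `||eps||_I` in place of `chi_d` (`acceptance_identity()`,
  `esjd_identity()`);
* `d -> Inf` limits `2 ell^2 pnorm(-ell / 2)` and `2 pnorm(-ell / 2)`,
  maximized at `ell ≈ 2.38` with acceptance ≈ 0.234
  (`asymptotic_esjd()`, `asymptotic_acceptance()`, `esjd_limit()`);
* grid optimisation of `ell` and the practical scaling
  `S_n = (ell / sqrt(d * n)) * M_n` (`optimize_ell()`, `tuning_table()`,
  `build_scaling()`);
* a generic seeded RWM sampler with acceptance/ESJD/ESS diagnostics
  (`run_chain()`, `chain_summary()`), an AR(1)-correlated Gaussian study
  (`run_ar1_study()`), and a Bayesian logistic regression demonstration on
  synthetic data (`generate_logistic()`, `fit_map()`,
  `tune_and_sample_posterior()`).

## Worked example

Dimension-dependent optima of the limiting matched-proposal chain:

```r
library(rwmscale)
tuning_table(c(1, 2, 5, 9, 10, 50))
#>    d     mode ell_hat      esjd acceptance_pct     method n_samples seed
#> 1  1 cholesky    2.43 0.7442026       43.83992 quadrature         0   NA
#> 2  2 cholesky    2.41 0.9499846       35.14401 quadrature         0   NA
#> 3  5 cholesky    2.40 1.1440220       28.38911 quadrature         0   NA
#> 4  9 cholesky    2.39 1.2182919       26.26260 quadrature         0   NA
#> 5 10 cholesky    2.39 1.2282631       25.96583 quadrature         0   NA
#> 6 50 cholesky    2.38 1.3050595       23.96662 quadrature         0   NA
```

The optimal `ell` falls from 2.43 at `d = 1` toward its limit 2.38, and the
optimal acceptance rate from 44% toward 23.4%. A real chain on a correlated
Gaussian target reproduces the theory:

```r
info <- ar1_info(0.6, 9)                       # tridiagonal information
tg   <- gaussian_target(ar1_covariance(0.6, 9))
tr   <- optimize_ell(9, "cholesky")            # ell_hat 2.39, acc 26.26%
ch   <- run_chain(tg, build_scaling(tr$ell_hat, 9, mode = "cholesky",
                                    info = info), 2e5, seed = 1)
summary(ch, metric = info)
#> Chain summary (200000 steps)
#>   acceptance rate  : 0.2645
#>   metric ESJD      : 1.2299 (se 0.0063)
#>   min ESS/iteration: 0.0333
```

Empirical acceptance 0.2645 and ESJD 1.23 match the limiting-chain values
(0.2626 and 1.218) within Monte Carlo error. The same machinery on a
synthetic logistic-regression posterior (`n = 4866`, `d = 9`, correlated
covariates), preconditioning with the inverse standardized observed
information at the MAP versus using an isotropic proposal:

```r
dat <- generate_logistic(logistic_gen_spec(n = 4866, d = 9, seed = 7))
tune_and_sample_posterior(dat, "cholesky", n_steps = 1e5, seed = 8)
#> Posterior RWM (cholesky mode, ell = 2.39)
#>   acceptance rate  : 0.2634
#>   min ESS/iteration: 0.0347
tune_and_sample_posterior(dat, "identity", n_steps = 1e5, seed = 8)
#> Posterior RWM (identity mode, ell = 5.74)
#>   acceptance rate  : 0.2697
#>   min ESS/iteration: 0.0153
```

The preconditioned sampler's acceptance rate (26.3%) lands on the limiting
value for `d = 9` (26.26%), and its minimum ESS per iteration is more than
double that of the tuned isotropic sampler, whose optimal `ell` balloons to
5.7 because an isotropic proposal must be tiny relative to the long axes of
a correlated target. See `vignettes/optimal-scaling.Rmd` for the model,
the numerical choices, and the limitations.

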
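---
title: "Tuning random walk Metropolis by large-sample asymptotics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tuning random walk Metropolis by large-sample asymptotics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model and its assumptions

Random walk Metropolis (RWM) proposes $\theta' = \theta + S\epsilon$ with
$\epsilon \sim N(0, 1)$ and accepts with probability
$\min\{1, \pi(\theta')/\pi(\theta)\}$. When $\pi$ is a Bayesian posterior
from $n$ observations of a sufficiently regular model, a Bernstein–von Mises
theorem makes the posterior close, in total variation, to a Gaussian centred
at an estimator $\hat\theta_n$ with covariance $I(\theta_0)^{-1}/n$, where
$I(\theta_0)$ is the Fisher information at the data-generating parameter.
Standardizing the chain by $z = \sqrt n(\theta - \hat\theta_n)$, RWM on the
posterior converges (as $n \to \infty$, with the dimension $d$ fixed) to RWM
on $N(0, I(\theta_0)^{-1})$ with proposal increment $\lambda M \epsilon$,
where $S_n = (\lambda/\sqrt n) M_n$ and $M_n M_n^T \to M M^T$.

This limiting chain is what `rwmscale` analyses. Writing
$\lambda = \ell/\sqrt d$, its stationary efficiency has closed expectation
forms in two canonical cases:

* **matched ("cholesky") proposal**, $M M^T = I(\theta_0)^{-1}$: the expected
  acceptance probability is $2\,E[\Phi(-(\ell/2\sqrt d)\,\chi_d)]$ and the
  information-metric expected squared jumping distance (ESJD) is
  $2\lambda^2 E[\chi_d^2\,\Phi(-(\lambda/2)\chi_d)]$, with $\chi_d$ a
  chi-distributed variable. Both are free of $I(\theta_0)$, so one tuning
  table serves every covariance structure.
* **isotropic ("identity") proposal**, $M = 1$: the same forms with
  $\chi_d$ replaced by the metric norm $\|\epsilon\|_{I(\theta_0)}$, which
  does depend on the correlation structure; strong correlation shrinks the
  optimal $\lambda$ and the achievable ESJD.

As $d \to \infty$ the matched-case ESJD converges to
$2\ell^2\Phi(-\ell/2)$, maximized at $\ell \approx 2.38$ where the
acceptance probability is $\approx 0.234$ — the classical rule, recovered
here for *any* covariance as long as the proposal is matched. For isotropic
proposals on targets whose normalized metric norm
$\|\epsilon\|_I^2/d$ obeys a law of large numbers with limit $L'$, the limit
is $2\ell^2 L' \Phi(-\ell\sqrt{L'}/2)$, so the optimum scales as
$1/\sqrt{L'}$ (`esjd_limit()`, `ar1_L_prime()`).

The practical guideline the package implements: fit a mode, take the
standardized observed information $\tilde I_n$ there, set
$S_n = (\hat\ell/\sqrt{dn}) M_n$ with $M_n M_n^T = \tilde I_n^{-1}$ and
$\hat\ell$ from the dimension-dependent tuning table. This is usable on the
very first run, before any trial chain.

## Parameters that matter

* `ell` ($\ell$): dimensionless step-size parameter; the per-axis proposal
  standard deviation is $\ell/\sqrt{dn}$. Optimal values run from about
  2.43 at $d = 1$ down to 2.38 as $d \to \infty$.
* `d`: parameter dimension; fixed in the asymptotics, it indexes the tuning
  table.
* `mode`: `"cholesky"` (matched, preferred under correlation) or
  `"identity"` (isotropic).
* `prior_sd` (logistic module, default 10): standard deviation of the
  independent Gaussian prior on each coefficient. Chosen weak so that at
  $n$ in the thousands the MAP essentially coincides with the MLE; the
  standardized observed information deliberately excludes prior curvature,
  matching its definition as an averaged log-likelihood Hessian.
* `burn_in_frac` (default 0.1): posterior chains start at the MAP, which is
  close to but not exactly a stationary draw; a 10% burn-in is discarded so
  stationary-expectation comparisons apply approximately.

## Numerical choices

* **Quadrature.** Expectations over $\chi_d$ are 1-D adaptive quadratures of
  the integrand against the chi density on
  $[\,F^{-1}_{\chi_d}(10^{-14}),\,F^{-1}_{\chi_d}(1-10^{-14})\,]$, absolute
  tolerance $10^{-12}$. The quantile-based interval matters: for large $d$
  the chi density is an $O(1)$-wide spike near $\sqrt d$ and adaptive rules
  on $[0, \sqrt d + 12]$ can miss it entirely. Quadrature results are
  seed-free and reproducible to full precision; the identity
  $2\,E[\Phi(-(\ell/2\sqrt d)\chi_d)] = 2 F_{t_d}(-\ell/2)$ (Student-t CDF)
  serves as an independent cross-check in the tests, never as the
  implementation.
* **Monte Carlo.** Default $10^6$ samples for single evaluations, with a
  mandatory explicit seed. For a general (non-scalar) metric,
  $\|\epsilon\|_I^2$ is sampled as $\epsilon^T I \epsilon$ — no 1-D
  reduction exists.
* **Grid search.** `optimize_ell()` uses step 0.01; the default window is
  $(0.5, 6)$ in cholesky mode and $(0.01, 20)$ in identity mode, wide
  because isotropic proposals on strongly correlated targets need large
  $\ell$. Identity-mode objectives are estimated with common random numbers
  ($10^5$ draws by default) shared across all grid points, searched coarse
  (step $\times 10$) then fine, which stabilizes the argmax of a very flat
  objective. Ties break toward the smallest $\ell$, and an argmax on the
  grid boundary is an error rather than an answer.
* **Flatness caveat.** Near its optimum the ESJD curve varies by only
  $10^{-6}$–$10^{-5}$ per 0.01 grid step while the acceptance rate moves by
  about 0.2 percentage points. Grid argmaxes from noisy (Monte Carlo)
  objective evaluations therefore wander one or two steps even at large
  sample sizes, dragging the reported acceptance-at-optimum with them;
  quadrature removes this wander. Reported $\hat\ell$ is rounded to two
  decimals; the unrounded grid value is kept internally.
* **Degenerate inputs.** $\ell = 0$ returns the analytic limits (acceptance
  1, ESJD 0) rather than raising; a constant chain coordinate yields ESS 0
  with a warning, not an error; log-domain acceptance (`log U <
  Δlog π`) avoids overflow, and a $-\infty$ proposal log-density is never
  accepted.
* **ESS estimator.** Geyer's initial monotone positive sequence on each
  marginal (FFT autocovariances, adjacent-lag pair sums truncated at the
  first nonpositive pair and forced nonincreasing). It is tuning-free and
  affine invariant; the performance measure reported across experiments is
  the minimum marginal ESS per iteration, since the metric ESJD is
  standardized by construction and cannot compare across correlation
  levels.
* **ESJD standard errors** use non-overlapping batch means with
  $\lfloor\sqrt T\rfloor$ batches; acceptance-rate comparisons in the tests
  use batch means on the acceptance indicators.
* **Newton MAP fit.** Full Newton steps with step-halving guarded by a
  *relative* log-posterior tolerance ($10^{-8}(1+|\log \pi|)$); an absolute
  guard stalls at realistic $n$ because the attainable improvement falls
  below floating-point resolution of a log posterior of magnitude $10^4$.
  Convergence is declared at gradient norm $< 10^{-8}$. Complete separation
  is reported when fitted probabilities degenerate ($p(1-p) < 10^{-12}$) or
  the estimate diverges.

## What the synthetic generator emulates — and what it does not

`generate_logistic()` produces design matrices with an intercept and
$d - 1$ unit-variance Gaussian covariates with AR(1) correlation
(default 0.5), and Bernoulli responses from true coefficients drawn once
per seed from $N(0, 0.5^2)$. Defaults $n = 4866$, $d = 9$ mirror the shape
of a realistic moderate-dimensional regression study: large enough that the
large-sample Gaussian approximation is accurate, correlated enough that
isotropic and preconditioned proposals separate clearly. What it does not
emulate: real covariates are rarely Gaussian (they are skewed, discrete,
collinear in structured ways), link misspecification, and outliers. Passing
tests therefore demonstrate the asymptotic mechanism — not that any
particular real dataset is inside the asymptotic regime, although the
regularity required is mild (a Bernstein–von Mises theorem).

## Design choices where the design was open

* The identity-mode tuning objective is the metric ESJD of the limiting
  chain, not the ESS; ESS-based tuning gives similar optima but needs
  chains rather than expectations, so it is kept as a diagnostic only.
* The AR(1) study runs 10 replicate chains of $2\times10^5$ steps per
  configuration with derived seeds; replicate scatter provides the standard
  errors for the invariance assertions.
* The weak-convergence behaviour of posterior chains is exercised at small
  to moderate $n$ (30–1000), where the finite-$n$ acceptance bias
  (≈ 0.07 at $n = 30$, $d = 9$) clearly dominates chain noise; at
  $n \gtrsim 10^3$ the bias is already at the noise floor of a
  $2\times10^4$-step chain, which is itself an informative statement about
  how quickly the limit sets in.
* Problem sizes throughout (chain lengths $10^5$–$2\times10^5$, Monte Carlo
  samples $10^5$–$10^6$) are chosen so each experiment runs in seconds to a
  few minutes on a single core while leaving every assertion dominated by
  the effect under test, not by Monte Carlo noise.

## A worked tour

```{r, eval = FALSE}
library(rwmscale)

## dimension-dependent optima of the limiting matched-proposal chain
tuning_table(c(1, 2, 5, 9, 10, 50))

## the d -> infinity rule
optimize(asymptotic_esjd, c(0.5, 6), maximum = TRUE)$maximum  # ~2.38
asymptotic_acceptance(2.38)                                   # ~0.234

## limiting chain vs a real chain on a correlated Gaussian
info <- ar1_info(0.6, 9)
tg   <- gaussian_target(ar1_covariance(0.6, 9))
tr   <- optimize_ell(9, "cholesky")
ch   <- run_chain(tg, build_scaling(tr$ell_hat, 9, mode = "cholesky",
                                    info = info), 2e5, seed = 1)
summary(ch, metric = info)     # acceptance ~ 26.3%, ESJD ~ 1.22

## posterior sampling with first-run preconditioning
dat <- generate_logistic(logistic_gen_spec(n = 4866, d = 9, seed = 7))
res <- tune_and_sample_posterior(dat, "cholesky", n_steps = 1e5, seed = 8)
res$summary
```

## Known limitations

* The asymptotics are $n \to \infty$ at fixed $d$; nothing here covers
  $d$ growing with $n$, heavy-tailed posteriors, or multimodality (where
  no Bernstein–von Mises theorem holds).
* Identity-mode theory values for general metrics are Monte Carlo only;
  their standard errors must be carried through comparisons.
* The sampler is deliberately plain R and single-stream; it is meant for
  studies of the tuning theory, not as a production MCMC engine.
* No within-chain adaptation: the point of the preconditioning guideline is
  precisely that a good proposal is available *before* the first run.
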
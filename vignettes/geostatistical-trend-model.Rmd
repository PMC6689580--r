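---
title: "The geostatistical trend model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The geostatistical trend model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(vaquitrend)
```

This vignette is the package's own account of the statistics it
implements: the model and its assumptions, the parameters that matter, the
sampler, what the synthetic-data generator does and does not emulate, and
the design decisions that were genuinely open.

## The model

The data are annual site summaries from a fixed monitoring grid: `W_ti`,
the mean number of clicks per day at site `i` in year `t`, computed over
the `n_ti` days sampled inside a fixed seasonal window (default Julian
days 170–231, 62 days). On the log scale `Y_ti = log(W_ti + 1)`,

$$Y_{ti} \mid \mu_t, Z_{ti} \sim N\!\left(\mu_t + Z_{ti},
\; \sigma^2_\epsilon / n_{ti}\right), \qquad
Z_t \sim \mathrm{MVN}\!\left(0, \sigma^2_z R(\rho)\right),
\qquad R_{ij} = e^{-3 h_{ij}/\rho}.$$

Three assumptions do the work. First, effort weighting: a site-year mean
over twice as many days is twice as precise, so sparse effort widens, and
never silently biases, the posterior. Second, spatial smoothing: site
deviations are correlated with an exponential correlogram in inter-site
distance `h_ij` (km), so a site with no data in some year is informed by
its neighbours — its `Z_ti` is drawn from the spatial conditional prior
given that year's observed sites. Third, separate year levels `mu_t` with
common variance components: each year gets its own surface, but the
smoothness (`rho`), spatial variance (`sigma2_z`) and observation variance
(`sigma2_eps`) are shared across years.

The quantities of scientific interest are derived per posterior draw:

$$B_t = \frac{1}{S}\sum_{i=1}^{S}\left(e^{\mu_t + Z_{ti}} - 1\right),
\qquad \lambda_{t_1,t_2} = B_{t_2}/B_{t_1},$$

with the average over all `S` grid sites, including sites unobserved in
year `t` (their `Z` comes from the spatial conditional prior, so `B_t` is
always an index for the full grid, comparable across years with different
coverage). `lambda` is oriented later-over-earlier throughout, so values
below one mean decline; the per-draw product of successive annual ratios
telescopes exactly to the full-span ratio, and the geometric-mean annual
change is the per-draw `(B_last/B_first)^{1/\text{years}}`.

Two edge rules: `B_t` can in principle be negative (when
`mu_t + Z_ti < 0` at many sites); draws with a non-positive denominator
are excluded from ratio summaries and their count reported, which is the
only ratio-safe choice and affects zero draws under realistic posteriors.

## Priors and tunable parameters

| parameter | meaning | default prior / value |
|---|---|---|
| `mu_t` | log-scale year level | Normal(0, variance 10^3) |
| `sigma2_eps` | per-day observation variance (log scale) | Inverse-Gamma(0.001, 0.001) |
| `sigma2_z` | spatial variance (log scale) | Inverse-Gamma(0.001, 0.001) |
| `rho` | practical range, km | Uniform(0.01, max(4 h_max, 10)) |

All are overridable through `default_priors()`, so an external prior
specification can be matched exactly. These are deliberately vague: on the
log-click scale the year levels live roughly in (0, 2), so a variance of
10^3 is flat over the relevant range, and `rerun_with_wider_priors()`
verifies insensitivity by refitting with every scale widened by a common
factor and reporting the largest shift in posterior-mean `lambda`. The
floor of 10 km on the range prior's upper bound keeps it proper on
degenerate (single-site) grids.

MCMC defaults (`mcmc_config()`) are one chain, 7500 burn-in iterations and
10 000 retained draws at thinning 100. Those mirror the monitoring
analysis the package was built around; the test suite uses far shorter
chains (300–4000 retained draws) because the collapsed sampler below mixes
quickly.

## The sampler

`fit_geostat()` is a Metropolis-within-Gibbs scheme with one deliberate
departure from the obvious conditional design. Given the variance
parameters, each year's `(mu_t, Z_t)` is drawn *jointly* from its exact
multivariate-normal full conditional (a precision-matrix Cholesky per
year). The variance parameters, however, are **not** updated conditionally
on `(mu, Z)`: with one observation per site-year the latent field and the
variances are so strongly coupled that conditional conjugate/random-walk
updates relax over tens of thousands of iterations (we observed the
observation-variance chain still drifting monotonically after 50 000
iterations on the packaged 46-site scenario). Instead the sampler
integrates `(mu, Z)` out analytically — per year, the observed vector is
marginally MVN with covariance
`mu_var J + sigma2_z R[obs, obs] + sigma2_eps diag(1/n)` — and moves
`(log sigma2_eps, log sigma2_z, log rho)` with a joint random-walk
Metropolis step against that marginal, followed by the exact conditional
draw of `(mu, Z)`. This marginal-then-conditional composition targets the
same joint posterior, and its mixing is governed by the (3-dimensional)
variance chain alone.

Because `sigma2_eps` and `sigma2_z` trade off along a ridge (their sum is
much better identified than their split), the proposal covariance is
learned during burn-in from the chain's own history (adaptive Metropolis:
scalar scale tuned to ~30% acceptance every 50 iterations, covariance
re-estimated every 200), and frozen at the end of burn-in so the retained
chain is a fixed-kernel Markov chain.

Numerical choices: the spatial correlation matrix gets a fixed `1e-10`
diagonal jitter before factorization; a failed Cholesky on a proposal
simply rejects it; starting values are data-based (year means, pooled
variance estimates, range = one third of the grid diameter) with
`"random"` and explicit-list alternatives; and the full draw sequence is
reproducible bit-for-bit from the seed. Fixing any subset of
`(sigma2_eps, sigma2_z, rho)` via `fix =` turns the model into a Gaussian
one with a closed-form posterior, which is how the sampler is validated in
the tests.

## Diagnostics

`diagnose()` reports, per monitored scalar chain, a Geweke z-score
(first 10% vs last 50%, variances from a lag-window spectral estimate) and
the Heidelberger–Welch pair (Cramér–von Mises stationarity with iterative
discarding of initial 10% increments up to 50%, then a relative-halfwidth
precision test). Implementation notes that matter:

* The long-run variance uses a Tukey–Hanning lag window truncated at
  `floor(sqrt(n))`. The rule was chosen by null calibration: across
  replicate white and AR(1) chains it keeps the Geweke statistic's spread
  close to 1 (longer windows inflate it noticeably). It is exposed as an
  argument of `spectrum0()`.
* By construction, the Heidelberger–Welch procedure *passes* a chain whose
  nonstationarity is confined to its first half (e.g. a level shift at the
  midpoint): the iterative discarding is designed to find a stationary
  suffix. Only changes in the final half of a chain can fail it. The tests
  assert both behaviours.
* A chain whose mean is statistically indistinguishable from zero makes
  the relative halfwidth criterion meaningless; it is reported as `NA`
  ("unreliable") rather than failed.
* Posterior predictive p-values are computed per observed site-year as the
  posterior expectation of `P(Y_rep <= Y_obs)`, i.e. the mean over draws
  of the Normal CDF at the observation. This is the deterministic
  expectation of the draw-a-replicate indicator (ties have measure zero on
  the continuous scale). Computed under the *true* generative parameters
  these are exactly uniform — that is what the calibration test checks.
  Computed from a posterior fitted to the same data they are conservative
  (clustered towards 0.5), the well-known double-use-of-data effect; on
  self-simulated data one should therefore read them as a misfit screen,
  not as calibrated tail probabilities.

`fit_geostat()` runs a quick Geweke screen (|z| > 3) automatically and
flags — but still returns — a suspect fit.

## Abundance projection and minimum-count updates

An independent abundance estimate reported as arithmetic mean and SD
(e.g. 66 ± 33 animals) is represented by the moment-matched lognormal:
`sigma^2 = log(1 + (sd/mean)^2)`, `mu = log(mean) - sigma^2/2`; the
back-transformed moments reproduce the inputs exactly and the median is
`exp(mu)` (59 for 66 ± 33). Trajectories pair the i-th prior draw with the
i-th joint posterior `lambda` draw — pairing by index preserves the
between-year posterior correlation of the ratios, while the prior draw is
independent of them because it comes from a separate survey — and multiply
through successive years exactly.

A verified minimum number alive in a year truncates the posterior:
trajectories whose projected abundance falls below any minimum are
discarded (rejection sampling), which is algebraically identical to
0/1 importance weighting on the full set — an identity the tests verify on
every run. Two open choices were resolved as follows:

* The comparison is on the continuous projected abundance (`N >= 7` means
  the real-valued draw is at least 7); a `rounding` argument provides
  floor/ceiling semantics for sensitivity analysis, since the source
  material does not state a convention.
* Because every `lambda` in a trajectory comes from one joint MCMC draw,
  conditioning on retention reweights *all* year pairs — including years
  before the minimum-count years. `updated_trend_table()` therefore
  recomputes every pair over the retained draw indices; this is the only
  mechanism by which pre-update year pairs can change, and with no
  truncation it reduces exactly to the plain table.

## The synthetic-data generator

`simulate_dataset()` draws data from the model's own generative structure:
per year a spatial deviation vector from `MVN(0, sigma2_z R(rho))`, an
effort pattern (whole-site missing years, more frequent in the first three
years to mimic the build-up phase of a real grid; per-day logger dropout
within the 62-day window), then log-scale annual means with variance
`sigma2_eps / n_ti`, back-transformed with `W = max(exp(Y) - 1, 0)`.

Defaults were fixed once, as what a monitoring statistician would call
realistic for this system: a 40 km grid of 46 sites, initial activity
4.37 clicks/day, spatial variance 0.6 (site-to-site factors of roughly
0.2–5 around the year mean), practical range 15 km, per-day observation
variance 2 (so a 50-day summary has log-scale SD ≈ 0.2), 5% daily dropout,
and year-one missingness of 20% falling to 3%. `scenario_paper_like()`
packages the headline validation fixture: annual change path
{0.67, 1.18, 0.49, 0.65, 0.41, 0.51, 0.42}, a ~98% seven-year decline.

Two generator-specific decisions deserve emphasis:

* **Truncation at zero.** The model's normal-on-log-scale puts mass on
  `W < 0`, which no real sensor can record; the generator clips at zero
  and reports the affected fraction. In deep-decline years the mean
  surface sits near zero and the clipped fraction is substantial (about a
  fifth of site-years in the packaged scenario), which makes the generator
  *harder* than the model's own assumptions — exactly the situation the
  real data present, where near-silent years produce many zero counts.
* **What "truth" means.** The realized ground truth for recovery testing
  is computed from the generator's actual draws on the data scale:
  `B_t = mean_i max(exp(mu_t + Z_ti) - 1, 0)`, and realized `lambda` as
  their ratios. A site's true expected click rate cannot be negative, so
  this — not the clip-free algebraic surface — is the estimand the fitted
  model targets; with spatial variance present the realized path can
  differ noticeably from the nominal `lambda` path used to build `mu_t`.

Daily disaggregation (`daily = TRUE`) gives each sampled day a
negative-binomial count with mean `W_ti` and configurable dispersion —
overdispersed counts whose expectation reproduces the annual summary —
so the full CSV-reading and aggregation path can be exercised; the model
itself only ever consumes annual summaries.

What the generator does **not** emulate: changes in detection range or
acoustic behaviour over time, oceanographic noise, within-season trends in
activity, and instrument-failure physics. Passing recovery tests therefore
demonstrate that the estimator inverts the model's own data-generating
process under realistic effort patterns — not that these field effects are
absent in real data.

## Validation problem sizes

The test suite validates at sizes chosen to make each check sharp:
exact-posterior comparison on a 2-site × 2-year toy with 4000 draws
(tolerance 3.5 Monte-Carlo standard errors); quadrature comparison on a
1-site toy; credible-interval coverage over 20 replicate fits of the full
46-site × 8-year scenario with 2000 retained draws each, pooling 140
nominal-95% intervals (pass bound 0.885, ~3.5 binomial SDs below nominal);
Geweke null calibration over 500 chains of length 10^4; predictive p-value
uniformity over the 368 site-years of a no-decline 46-site scenario.

## Known limitations

* The split between `sigma2_eps` and `sigma2_z` is weakly identified with
  one summary per site-year — only spatial correlation separates them —
  and their marginal posteriors can sit far from generator values while
  `mu_t`, `B_t` and all `lambda` remain well calibrated. Conclusions
  should rest on the trend quantities, not on the variance components.
* In near-zero-activity years, `B_t` is a small difference of exponentials
  and its posterior is wide and right-skewed; annual ratios out of such
  years are honest but unstable, and the geometric-mean change over the
  span is the more reliable summary.
* The model treats the click index as proportional to abundance; the
  projection inherits that assumption, plus independence between the
  abundance prior and the trend posterior.
* One chain with seeded reproducibility is the designed workflow;
  multi-chain potential-scale-reduction diagnostics are out of scope.
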
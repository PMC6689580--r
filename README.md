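# vaquitrend

Bayesian geostatistical trend analysis for gridded passive acoustic
monitoring data.

## The problem

Small cetaceans that are hard to survey visually can be monitored with
fixed grids of autonomous echolocation-click loggers. The motivating
application is the summer monitoring programme for the vaquita porpoise:
46 logger sites sampled over the same 62-day window (Julian days 170–231)
every year, with the mean number of validated clicks per site per day as
the index of population activity. Effort is unbalanced — whole sites can
be missing in a year and loggers drop days within a season — so raw
cross-site means are biased and a model-based estimate of the between-year
trend is needed.

`vaquitrend` provides, for analysts running such programmes:

* aggregation of daily click-count records into site-by-year summaries,
* a hierarchical geostatistical trend model fitted by MCMC,
* convergence diagnostics and posterior predictive checks,
* derived annual change ratios with decline probabilities,
* projection of an independent abundance estimate along the posterior
  trend, with rejection-sampling updates from minimum-known-alive counts,
* a synthetic-data generator with known ground truth for validation.

## The model

Let `W_ti` be the mean clicks per day at site `i` in year `t`, averaged
over `n_ti` sampled days, and `Y_ti = log(W_ti + 1)`. Then

    Y_ti | mu_t, Z_ti ~ Normal(mu_t + Z_ti, sigma2_eps / n_ti)
    Z_t             ~ MVN(0, sigma2_z * R(rho)),   R_ij = exp(-3 h_ij / rho)

where `mu_t` is the year effect, `Z_t` the vector of spatially correlated
site deviations, `h_ij` the inter-site distance in km and `rho` the
practical range (correlation falls to exp(-3) ≈ 0.05 at distance `rho`).
Sites with more sampling days get proportionally smaller observation
variance; sites with no data in a year borrow strength from their
neighbours through `R(rho)`.

The derived quantities are the annual activity index and its ratios:

    B_t = (1/S) * sum_i (exp(mu_t + Z_ti) - 1),    lambda_{t1,t2} = B_t2 / B_t1

with `lambda < 1` indicating decline and `(1 - lambda) * 100` the percent
decline. Abundance trajectories pair draws from a moment-matched lognormal
abundance prior with joint posterior `lambda` draws; trajectories that
violate verified minimum-alive counts are discarded and all summaries
recomputed on the retained set.

## Worked example

Simulate a realistic monitoring study (46 sites, 2011–2018, a ~98% total
decline with patchy early-year effort), fit the model, and project
abundance with minimum-count updates:

```r
library(vaquitrend)

sim <- simulate_dataset(scenario_paper_like(seed = 29), daily = TRUE)
fit <- fit_geostat(sim$dataset,
                   config = mcmc_config(n_burn = 1500, n_keep = 2000,
                                        thin = 3, seed = 1))
trend_table(fit)
#>                   period lambda (95% CRI) P(declining) % P(declining >20%/yr) %
#>                2011-2012 0.74 (0.48-1.09)           93.7                   68.5
#>                2012-2013 1.52 (0.99-2.20)            2.8                    0.0
#>                2013-2014 0.49 (0.33-0.71)          100.0                   99.4
#>                2014-2015 0.52 (0.30-0.78)           99.9                   98.0
#>                2015-2016 0.80 (0.42-1.36)           83.5                   56.6
#>                2016-2017 0.87 (0.42-1.53)           73.2                   45.4
#>                2017-2018 0.77 (0.29-1.65)           82.5                   61.5
#>  geometric mean per-year 0.74 (0.66-0.80)          100.0                   97.4
```

Each row is the posterior for one annual change ratio: for example the
fitted 2013–2014 change of 0.49 (a 51% decline) against the generator's
realized 0.41, with essentially certain decline. The generator's realized
annual ratios for this seed are {0.73, 1.47, 0.41, 0.69, 0.64, 0.67,
0.76}, and each falls inside its 95% credible interval. The geometric-mean
row summarizes the whole span: a posterior-mean 26% decline per year.

```r
prior <- lognormal_from_moments(66, 33)
prior
#> Lognormal abundance prior: mean 66.0, sd 33.0 (median 59.0 animals)

traj <- project_abundance(prior, lambda_streams(fit, from = 2015),
                          start_year = 2015, seed = 1)
upd  <- apply_minimum_counts(traj, c("2017" = 7, "2018" = 6))
upd
#> Trajectory set: 2000 trajectories, years 2015-2018; 1969 retained

summarize_abundance(upd, 2018)
#> 2018 post-update: mean 32.1  median 26.6  95% CRI 8.2-89.1
```

The prior represents an independent mark of 66 ± 33 animals in 2015
(median 59); trajectories multiply its draws by the joint annual-change
draws, and the minimum-count update discards the 31 trajectories that
contradict at least 7 animals alive in 2017 and 6 in 2018.

`run_pipeline(config)` chains all stages (prepare/simulate, fit, diagnose,
trend, project, update) from a single list or YAML file and writes every
table as headered CSV with a JSON metadata sidecar.

## Using the real monitoring dataset

The functions read the canonical CSV schema (`site_id, date, clicks, dpm`
for detections; `site_id, date` for effort; `site_id, easting_km,
northing_km` for sites), and a column-mapping YAML adapts files with other
headers. The published vaquita monitoring tables (distributed as the
article's electronic supplementary material, not redistributed here) can be
dropped into `inst/extdata/supplementary/` as `detections.csv`,
`effort.csv`, `sites.csv`; after reinstalling, the test
`test-acceptance.R: "the monitoring dataset reproduces the published
summaries"` runs the full published analysis against them.

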
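test_that("log transform maps click means as intended", {
  expect_equal(log_transform(0), 0)
  expect_equal(log_transform(exp(1) - 1), 1)
  expect_equal(log_transform(4.37), log(5.37))
  expect_true(all(diff(log_transform(seq(0, 50, by = 0.5))) > 0))
  expect_error(log_transform(-0.1), "nonnegative")
})

test_that("exponential correlation has the stated kernel and limits", {
  g <- tiny_grid(4, spacing = 5)
  rho <- 7
  R <- exp_correlation(g, rho)
  expect_equal(diag(R), rep(1, 4), ignore_attr = TRUE)
  expect_equal(R, t(R))
  h <- site_distances(g)
  expect_equal(R[1, 2], exp(-3 * h[1, 2] / rho))
  # at distance rho the correlation is exp(-3)
  g2 <- site_grid(1:2, c(0, rho), c(0, 0))
  expect_equal(exp_correlation(g2, rho)[1, 2], exp(-3))
  # rho -> infinity: all entries -> 1
  expect_true(all(exp_correlation(g, 1e9) > 0.999))
  # positive definite for distinct sites
  expect_true(all(eigen(R, only.values = TRUE)$values > 0))
  expect_error(exp_correlation(g, 0), "positive")
  gd <- site_grid(1:2, c(0, 0), c(0, 0))
  expect_warning(exp_correlation(gd, 5), "duplicated")
})

test_that("log posterior is maximized at the observation on a flat-prior toy", {
  g <- site_grid("a", 0, 0)
  ds <- monitoring_dataset(g, data.frame(year = 2011, site_id = "a",
                                         W = 4, n = 10))
  pr <- default_priors(g, mu_var = 1e8)
  y <- log_transform(4)
  lp <- function(mu) log_posterior(
    list(mu = mu, Z = matrix(0, 1, 1), sigma2_eps = 1,
         sigma2_z = 0.1, rho = 5), ds, pr)
  mu_grid <- seq(y - 1, y + 1, by = 0.001)
  vals <- vapply(mu_grid, lp, 0)
  expect_equal(mu_grid[which.max(vals)], y, tolerance = 0.002)
})

test_that("more sampling days increase the likelihood of an exact fit", {
  g <- site_grid("a", 0, 0)
  mk <- function(n) monitoring_dataset(
    g, data.frame(year = 2011, site_id = "a", W = 4, n = n))
  pr <- default_priors(g)
  params <- list(mu = log_transform(4), Z = matrix(0, 1, 1),
                 sigma2_eps = 1, sigma2_z = 0.1, rho = 5)
  expect_gt(log_posterior(params, mk(20), pr),
            log_posterior(params, mk(10), pr))
})

test_that("log posterior agrees with an independent MVN density", {
  skip_if_not_installed("mvtnorm")
  g <- tiny_grid(4)
  s <- data.frame(year = rep(c(2011, 2012), each = 4),
                  site_id = rep(1:4, 2),
                  W = c(3, 5, 2, 4, 1, 2, 0.5, 1.5),
                  n = c(10, 20, 30, 40, 15, 25, 35, 45))
  ds <- monitoring_dataset(g, s)
  pr <- default_priors(g)
  set.seed(1)
  params <- list(mu = c(1.2, 0.6),
                 Z = matrix(rnorm(8, 0, 0.3), 2, 4),
                 sigma2_eps = 1.3, sigma2_z = 0.5, rho = 9)
  R <- exp_correlation(g, params$rho)
  Y <- matrix(log_transform(s$W), 2, 4, byrow = TRUE)
  n <- matrix(s$n, 2, 4, byrow = TRUE)
  manual <- 0
  for (t in 1:2) {
    manual <- manual +
      sum(dnorm(Y[t, ], params$mu[t] + params$Z[t, ],
                sqrt(params$sigma2_eps / n[t, ]), log = TRUE)) +
      mvtnorm::dmvnorm(params$Z[t, ], sigma = params$sigma2_z * R, log = TRUE)
  }
  manual <- manual +
    sum(dnorm(params$mu, pr$mu_mean, sqrt(pr$mu_var), log = TRUE)) +
    vaquitrend:::inv_gamma_logd(params$sigma2_eps, pr$eps_shape, pr$eps_rate) +
    vaquitrend:::inv_gamma_logd(params$sigma2_z, pr$z_shape, pr$z_rate) -
    log(pr$rho_max - pr$rho_min)
  expect_equal(log_posterior(params, ds, pr), manual, tolerance = 1e-6)
})

test_that("sampler posterior matches grid quadrature on a one-site toy", {
  g <- site_grid("a", 0, 0)
  ds <- monitoring_dataset(g, data.frame(year = 2011, site_id = "a",
                                         W = 4, n = 10))
  pr <- default_priors(g)
  fix <- list(sigma2_eps = 1.5, sigma2_z = 1e-8, rho = 5)
  fit <- fit_geostat(ds, pr, quick_config(seed = 2, n_keep = 4000),
                     fix = fix, diagnose_fit = FALSE)
  # quadrature over mu with Z pinned at ~0 by the tiny spatial variance
  mu_grid <- seq(-3, 6, by = 0.002)
  logd <- vapply(mu_grid, function(m) log_posterior(
    list(mu = m, Z = matrix(0, 1, 1), sigma2_eps = fix$sigma2_eps,
         sigma2_z = fix$sigma2_z, rho = fix$rho), ds, pr), 0)
  w <- exp(logd - max(logd))
  quad_mean <- sum(mu_grid * w) / sum(w)
  expect_equal(mean(fit$mu[, 1]), quad_mean, tolerance = 0.03)
})

test_that("with no spatial effect the posterior mean is the weighted mean", {
  # sigma2_z -> 0, single year, near-flat prior: conjugate normal closed form
  g <- tiny_grid(3)
  s <- data.frame(year = 2011, site_id = 1:3, W = c(2, 5, 9),
                  n = c(10, 30, 60))
  ds <- monitoring_dataset(g, s)
  pr <- default_priors(g, mu_var = 1e8)
  fit <- fit_geostat(ds, pr, quick_config(seed = 4, n_keep = 4000),
                     fix = list(sigma2_eps = 2, sigma2_z = 1e-9, rho = 5),
                     diagnose_fit = FALSE)
  y <- log_transform(s$W)
  expect_equal(mean(fit$mu[, 1]), weighted.mean(y, s$n), tolerance = 0.01)
})

test_that("identical configuration reproduces the draw sequence exactly", {
  sim <- small_sim(seed = 5)
  cfg <- quick_config(seed = 77, n_keep = 50, n_burn = 50)
  f1 <- fit_geostat(sim$dataset, config = cfg, diagnose_fit = FALSE)
  f2 <- fit_geostat(sim$dataset, config = cfg, diagnose_fit = FALSE)
  expect_identical(f1$mu, f2$mu)
  expect_identical(f1$Z, f2$Z)
  expect_identical(f1$rho, f2$rho)
})

test_that("posterior summaries are invariant to site relabeling", {
  sim <- small_sim(seed = 6, n_sites = 8)
  ds <- sim$dataset
  perm <- c(5, 3, 8, 1, 7, 2, 6, 4)
  g2 <- site_grid(ds$grid$site_id[perm], ds$grid$easting_km[perm],
                  ds$grid$northing_km[perm])
  ds2 <- monitoring_dataset(g2, ds$summaries, ds$core_window)
  cfg <- quick_config(seed = 10, n_keep = 1500, n_burn = 500)
  f1 <- fit_geostat(ds, config = cfg, diagnose_fit = FALSE)
  f2 <- fit_geostat(ds2, config = cfg, diagnose_fit = FALSE)
  expect_equal(colMeans(f1$mu), colMeans(f2$mu), tolerance = 0.05)
  lam1 <- colMeans(lambda_streams(f1))
  lam2 <- colMeans(lambda_streams(f2))
  expect_equal(lam1, lam2, tolerance = 0.08)
})

test_that("doubling effort tightens the annual-mean posteriors", {
  sim <- simulate_dataset(synthetic_truth(
    n_sites = 12, extent_km = 20, lambda = c(0.7, 1.1, 0.6), B_start = 5,
    sigma2_eps = 1, sigma2_z = 0.4, rho = 10, missing_year_prob = 0,
    day_dropout_prob = 0.6, seed = 8))
  ds <- sim$dataset
  ds2 <- ds
  ds2$summaries$n <- ds2$summaries$n * 2L
  # fix the variance parameters so the mu posteriors are exact Gaussians and
  # the comparison isolates the effort weighting
  cfg <- quick_config(seed = 3, n_keep = 3000, n_burn = 300)
  fx <- list(sigma2_eps = 1, sigma2_z = 0.4, rho = 10)
  f1 <- fit_geostat(ds, config = cfg, fix = fx, diagnose_fit = FALSE)
  f2 <- fit_geostat(ds2, config = cfg, fix = fx, diagnose_fit = FALSE)
  width <- function(f) mean(apply(f$mu, 2, function(x)
    diff(quantile(x, c(0.025, 0.975)))))
  expect_lt(width(f2), width(f1))
})

test_that("missing site-years receive spatial-prior draws covering all sites", {
  tr <- synthetic_truth(n_sites = 10, extent_km = 15, lambda = c(0.8, 0.9),
                        sigma2_eps = 1, sigma2_z = 0.4, rho = 10,
                        missing_year_prob = c(0.4, 0, 0), seed = 21)
  sim <- simulate_dataset(tr)
  n_missing <- 10 - sum(sim$dataset$summaries$year == 2011)
  expect_gt(n_missing, 0)  # the seed produces missing sites in year 1
  fit <- fit_geostat(sim$dataset, config = quick_config(seed = 2, n_keep = 200),
                     diagnose_fit = FALSE)
  expect_equal(dim(fit$Z), c(200L, 3L, 10L))
  expect_true(all(is.finite(fit$Z)))
})

test_that("wider priors leave the trend estimates essentially unchanged", {
  sim <- small_sim(seed = 12)
  cfg <- quick_config(seed = 6, n_keep = 1200, n_burn = 500)
  base <- fit_geostat(sim$dataset, config = cfg, diagnose_fit = FALSE)
  cmp <- rerun_with_wider_priors(sim$dataset, config = cfg,
                                 widen_factor = 10, baseline = base)
  expect_lt(cmp$max_abs_diff, 0.1)
  # widen_factor 1 with the same seed reproduces the baseline path exactly
  cmp1 <- rerun_with_wider_priors(sim$dataset, config = cfg,
                                  widen_factor = 1, baseline = base)
  expect_equal(cmp1$max_abs_diff, 0)
})
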
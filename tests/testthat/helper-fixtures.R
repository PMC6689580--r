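# Shared fixture builders: everything is generated in code at test time.

tiny_grid <- function(n = 4, spacing = 5) {
  idx <- seq_len(n) - 1
  site_grid(seq_len(n), easting_km = (idx %% 2) * spacing,
            northing_km = (idx %/% 2) * spacing)
}

# Write a small canonical-schema season to CSV files; returns the paths.
# Two sites, June-August 2011; site 2 misses the last day of effort.
write_toy_season <- function(dir = withr::local_tempdir(.local_envir = parent.frame()),
                             clicks1 = c(2, 4, 6), clicks2 = c(0, 1, 3)) {
  days <- as.Date(c("2011-06-19", "2011-07-01", "2011-08-19"))
  eff <- data.frame(
    site_id = c(rep(1, 3), rep(2, 2)),
    date = c(days, days[1:2])
  )
  det <- data.frame(
    site_id = c(rep(1, 3), rep(2, 2)),
    date = c(days, days[1:2]),
    clicks = c(clicks1, clicks2[1:2]),
    dpm = pmin(c(clicks1, clicks2[1:2]), 1440)
  )
  det <- det[det$clicks > 0, ]
  paths <- list(detections = file.path(dir, "det.csv"),
                effort = file.path(dir, "eff.csv"), dir = dir)
  write.csv(det, paths$detections, row.names = FALSE)
  write.csv(eff, paths$effort, row.names = FALSE)
  paths
}

# Minimal stand-in for a geostat_draws object with prescribed mu draws
# (draws x years) and Z array (draws x years x sites).
fake_draws <- function(mu, Z, years = NULL, sites = NULL) {
  if (is.null(years)) years <- seq(2011, length.out = ncol(mu))
  if (is.null(sites)) sites <- as.character(seq_len(dim(Z)[3]))
  colnames(mu) <- years
  structure(list(mu = mu, Z = Z,
                 sigma2_eps = rep(1, nrow(mu)),
                 sigma2_z = rep(1, nrow(mu)),
                 rho = rep(10, nrow(mu)),
                 years = as.integer(years), sites = sites, fix = list()),
            class = "geostat_draws")
}

# Small, fast model-matched dataset for sampler tests.
small_sim <- function(seed = 42, lambda = c(0.7, 1.1, 0.6),
                      n_sites = 12, ...) {
  simulate_dataset(synthetic_truth(
    n_sites = n_sites, extent_km = 20, lambda = lambda, B_start = 5,
    sigma2_eps = 1, sigma2_z = 0.4, rho = 10,
    missing_year_prob = 0, day_dropout_prob = 0, seed = seed, ...))
}

quick_config <- function(seed = 1, n_keep = 400, n_burn = 300, thin = 1) {
  mcmc_config(n_burn = n_burn, n_keep = n_keep, thin = thin, seed = seed)
}
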
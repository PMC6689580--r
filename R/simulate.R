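#' Ground truth specification for a synthetic monitoring study
#'
#' Bundles everything the generator needs to simulate a monitoring dataset
#' with the statistical structure the trend model assumes: a fixed site
#' grid, per-year log-scale means following a multiplicative decline path,
#' spatially autocorrelated site deviations, effort-dependent observation
#' noise, and realistic missing-effort patterns (whole sites missing in a
#' year, short within-season gaps).
#'
#' The annual means are derived from an initial activity level and a true
#' change path: B_1 = `B_start`, B_{t+1} = lambda_t * B_t, and
#' mu_t = log(1 + B_t), so the zero-deviation surface reproduces the stated
#' path exactly.
#'
#' @param n_sites number of monitoring sites (>= 2).
#' @param extent_km side length of the (square) study area in km.
#' @param start_year first monitoring year.
#' @param lambda vector of true per-year change ratios (length = years - 1).
#' @param B_start true cross-site mean clicks per day in the first year.
#' @param sigma2_eps independent (per-day) observation variance on the log
#'   scale; an annual mean over n days has variance sigma2_eps / n.
#' @param sigma2_z variance of the spatial random effect.
#' @param rho practical range of the spatial correlation, km.
#' @param missing_year_prob per-year probability that a site records no data
#'   at all that year; recycled to the number of years. The default makes
#'   the first three years patchier, mimicking the build-up phase of a real
#'   monitoring grid.
#' @param day_dropout_prob probability that any given day of a deployed
#'   logger is lost (servicing gaps, failures).
#' @param n_days length of the core sampling window in days.
#' @param seed RNG seed for the generator.
#' @return list of class `synthetic_truth`.
#' @export
synthetic_truth <- function(n_sites = 46, extent_km = 40,
                            start_year = 2011,
                            lambda = rep(0.66, 7), B_start = 4.37,
                            sigma2_eps = 2, sigma2_z = 0.6, rho = 15,
                            missing_year_prob = c(0.2, 0.2, 0.15,
                                                  rep(0.03, max(length(lambda) - 2, 0))),
                            day_dropout_prob = 0.05,
                            n_days = 62L, seed = 1L) {
  stopifnot(n_sites >= 2, all(lambda > 0), B_start > 0,
            sigma2_eps >= 0, sigma2_z >= 0, rho > 0,
            all(missing_year_prob >= 0 & missing_year_prob <= 1),
            day_dropout_prob >= 0, day_dropout_prob < 1)
  n_years <- length(lambda) + 1L
  B <- B_start * cumprod(c(1, lambda))
  structure(list(
    n_sites = as.integer(n_sites), extent_km = extent_km,
    years = start_year + seq_len(n_years) - 1L,
    lambda = lambda, B = B, mu = log1p(B),
    sigma2_eps = sigma2_eps, sigma2_z = sigma2_z, rho = rho,
    missing_year_prob = rep_len(missing_year_prob, n_years),
    day_dropout_prob = day_dropout_prob,
    n_days = as.integer(n_days), seed = as.integer(seed)
  ), class = "synthetic_truth")
}

#' Paper-like synthetic scenario
#'
#' The packaged validation fixture: 46 sites on a 40 km grid monitored
#' 2011-2018, an initial activity level of 4.37 clicks per day, and a true
#' change path of {0.67, 1.18, 0.49, 0.65, 0.41, 0.51, 0.42} — a decline of
#' about 99% over seven years — with patchier effort in the first three
#' years. Used throughout the test suite for parameter-recovery checks.
#'
#' @param seed RNG seed (fixed default so the fixture is reproducible).
#' @param ... overrides passed on to [synthetic_truth()].
#' @return a `synthetic_truth`.
#' @export
scenario_paper_like <- function(seed = 190598L, ...) {
  synthetic_truth(
    n_sites = 46, extent_km = 40, start_year = 2011,
    lambda = c(0.67, 1.18, 0.49, 0.65, 0.41, 0.51, 0.42),
    B_start = 4.37, sigma2_eps = 2, sigma2_z = 0.6, rho = 15,
    seed = seed, ...)
}

#' Simulate a systematic site grid
#'
#' Sites are laid out row-by-row on a regular square lattice covering the
#' stated extent, taking the first `n_sites` lattice points — the synthetic
#' analogue of a systematic monitoring design.
#'
#' @param truth a `synthetic_truth`.
#' @return a [site_grid()].
#' @export
simulate_grid <- function(truth) {
  n <- truth$n_sites
  nx <- ceiling(sqrt(n))
  spacing <- if (nx > 1) truth$extent_km / (nx - 1) else 0
  if (spacing == 0)
    warning("zero spatial extent: all sites share one coordinate",
            call. = FALSE)
  idx <- seq_len(n) - 1L
  site_grid(seq_len(n),
            easting_km = (idx %% nx) * spacing,
            northing_km = (idx %/% nx) * spacing)
}

#' Simulate a monitoring dataset with known ground truth
#'
#' Draws, for each year: the spatial deviation vector Z_t from
#' MVN(0, sigma2_z R(rho)); the effort pattern (whole-site missing years,
#' then per-day dropout within the window, giving n_ti days); and the
#' log-scale annual mean Y_ti ~ Normal(mu_t + Z_ti, sigma2_eps / n_ti). The
#' click-scale summary is W_ti = max(exp(Y_ti) - 1, 0); the truncation at
#' zero is a generator-side concession (the model's normal on the log scale
#' can produce Y < 0) and the fraction of site-years affected is reported.
#'
#' With `daily = TRUE` the annual summaries are additionally disaggregated
#' into per-day records: each sampled day receives a negative-binomial click
#' count with mean W_ti (dispersion `daily_size`), so the daily series has
#' realistic overdispersion and its expectation reproduces W_ti; the
#' returned dataset is then re-aggregated from those records, exercising the
#' full IO path.
#'
#' @param truth a `synthetic_truth`.
#' @param daily also generate per-day records (default FALSE).
#' @param daily_size negative-binomial dispersion for daily counts.
#' @return list of class `synthetic_dataset`: `dataset` (a
#'   `monitoring_dataset`), `records` (daily records or NULL), and `truth` —
#'   the input spec augmented with the realized `Z`, realized `B`
#'   (cross-site mean of exp(mu + Z) - 1 over the actual draws), realized
#'   `lambda`, and `truncated_fraction`.
#' @export
simulate_dataset <- function(truth, daily = FALSE, daily_size = 5) {
  grid <- simulate_grid(truth)
  set.seed(truth$seed)
  S <- truth$n_sites
  T_ <- length(truth$years)
  R <- exp_correlation(grid, truth$rho)
  U <- chol(R + diag(1e-10, S))
  Z <- matrix(stats::rnorm(T_ * S), T_, S) %*% U * sqrt(truth$sigma2_z)

  n <- matrix(0L, T_, S)
  for (t in seq_len(T_)) {
    present <- stats::runif(S) >= truth$missing_year_prob[t]
    n[t, present] <- stats::rbinom(sum(present), truth$n_days,
                                   1 - truth$day_dropout_prob)
  }
  obs <- n > 0

  mean_mat <- sweep(Z, 1, truth$mu, `+`)
  Y <- matrix(NA_real_, T_, S)
  Y[obs] <- stats::rnorm(sum(obs), mean_mat[obs],
                         sqrt(truth$sigma2_eps / n[obs]))
  W <- expm1(Y)
  truncated <- sum(W < 0, na.rm = TRUE) / max(sum(obs), 1)
  W[W < 0] <- 0

  idx <- which(obs, arr.ind = TRUE)
  summaries <- data.frame(
    year = truth$years[idx[, 1]],
    site_id = grid$site_id[idx[, 2]],
    W = W[idx], n = n[idx],
    stringsAsFactors = FALSE
  )
  summaries <- summaries[order(summaries$year, summaries$site_id), ]
  rownames(summaries) <- NULL

  records <- NULL
  if (daily) {
    window <- c(170L, 170L + truth$n_days - 1L)
    recs <- lapply(seq_len(nrow(summaries)), function(k) {
      yr <- summaries$year[k]
      days <- sort(sample(seq.int(window[1], window[2]), summaries$n[k]))
      clicks <- stats::rnbinom(length(days), mu = summaries$W[k],
                               size = daily_size)
      data.frame(site_id = summaries$site_id[k],
                 date = as.Date(sprintf("%d-01-01", yr)) + days - 1L,
                 clicks = clicks,
                 dpm = pmin(clicks, 1440L),
                 sampled = TRUE,
                 stringsAsFactors = FALSE)
    })
    records <- do.call(rbind, recs)
    class(records) <- c("daily_records", "data.frame")
    dataset <- annualize(records, grid, core_window = window)
  } else {
    dataset <- monitoring_dataset(grid, summaries)
  }

  # Realized truth on the data scale: a site's true expected mean daily
  # click count is max(exp(mu_t + Z_ti) - 1, 0) -- click rates cannot be
  # negative -- so the realized annual activity index averages these.
  B_real <- rowMeans(pmax(expm1(mean_mat), 0))
  truth$Z <- Z
  truth$B_realized <- B_real
  truth$lambda_realized <- B_real[-1] / B_real[-T_]
  truth$truncated_fraction <- truncated
  structure(list(dataset = dataset, records = records, truth = truth),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic monitoring dataset: %d sites, %d years (seed %d)\n",
    x$truth$n_sites, length(x$truth$years), x$truth$seed))
  cat(sprintf("True total change %.4f; %.1f%% of site-years truncated at 0\n",
              prod(x$truth$lambda), 100 * x$truth$truncated_fraction))
  invisible(x)
}

#' Write a synthetic dataset in the canonical CSV schema
#'
#' Emits the same file layout [load_daily_records()] reads (detections,
#' effort, sites CSVs) plus a JSON sidecar with the generator truth, so the
#' whole pipeline can be driven from files.
#'
#' @param sim a `synthetic_dataset` generated with `daily = TRUE`.
#' @param dir output directory (created if needed).
#' @return named vector of the paths written, invisibly.
#' @export
write_synthetic <- function(sim, dir) {
  if (is.null(sim$records))
    stop("synthetic dataset has no daily records; ",
         "rerun simulate_dataset(daily = TRUE)", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  det <- sim$records[sim$records$clicks > 0,
                     c("site_id", "date", "clicks", "dpm")]
  eff <- sim$records[, c("site_id", "date")]
  paths <- c(detections = file.path(dir, "detections.csv"),
             effort = file.path(dir, "effort.csv"),
             sites = file.path(dir, "sites.csv"),
             truth = file.path(dir, "truth.json"))
  utils::write.csv(det, paths["detections"], row.names = FALSE)
  utils::write.csv(eff, paths["effort"], row.names = FALSE)
  utils::write.csv(as.data.frame(sim$dataset$grid), paths["sites"],
                   row.names = FALSE)
  truth <- unclass(sim$truth)
  truth$Z <- NULL
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
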
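#' End-to-end trend and abundance analysis
#'
#' Chains the full analysis: data preparation (from CSV files or the
#' synthetic generator), model fitting, convergence diagnostics, trend
#' summaries, abundance projection and the minimum-count update, writing
#' every tabular output as headered CSV plus a JSON metadata sidecar
#' recording the seed and configuration. Any stage failure aborts with the
#' stage named.
#'
#' @param config named list, or path to a YAML file holding one, with
#'   elements (all optional unless noted):
#'   \describe{
#'     \item{data}{list with `detections`, `effort`, `sites` CSV paths (and
#'       optionally `col_map`); mutually exclusive with `synthetic`.}
#'     \item{synthetic}{list of arguments to [synthetic_truth()]; used when
#'       no `data` is given (default: [scenario_paper_like()]).}
#'     \item{core_window}{Julian-day window, default c(170, 231).}
#'     \item{priors}{named overrides merged into [default_priors()].}
#'     \item{mcmc}{list of arguments to [mcmc_config()].}
#'     \item{abundance}{list with `mean`, `sd`, `year` of the independent
#'       abundance estimate; default mean 66, sd 33 at year 2015.}
#'     \item{minimums}{named list/vector of minimum-known-alive counts by
#'       year, e.g. `list("2017" = 7, "2018" = 6)`; empty to skip the
#'       update.}
#'     \item{out_dir}{output directory (required).}
#'     \item{seed}{overall seed, also used for the projection pairing.}
#'   }
#' @return invisibly, a list with every intermediate object: `dataset`,
#'   `fit`, `diagnostics`, `trend`, `trajectories`, `trend_updated`,
#'   `abundance_pre`, `abundance_post`, `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) stop("config$out_dir is required", call. = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  core_window <- if (is.null(config$core_window)) c(170L, 231L) else
    as.integer(config$core_window)

  # --- prepare ---
  res <- list()
  prepared <- stage("prepare", {
    if (!is.null(config$data)) {
      d <- config$data
      sites <- utils::read.csv(d$sites, stringsAsFactors = FALSE)
      grid <- site_grid(sites$site_id, sites$easting_km, sites$northing_km)
      rec <- load_daily_records(d$detections, d$effort,
                                col_map = d$col_map, grid = grid)
      utils::write.csv(effort_series(rec),
                       file.path(out, "effort_series.csv"), row.names = FALSE)
      list(dataset = annualize(rec, grid, core_window), truth = NULL)
    } else {
      args <- if (is.null(config$synthetic)) list() else config$synthetic
      args$seed <- if (is.null(args$seed)) seed else args$seed
      truth <- do.call(synthetic_truth, args)
      sim <- simulate_dataset(truth, daily = TRUE)
      utils::write.csv(effort_series(sim$records),
                       file.path(out, "effort_series.csv"), row.names = FALSE)
      list(dataset = sim$dataset, truth = sim$truth)
    }
  })
  res$dataset <- prepared$dataset
  res$truth <- prepared$truth
  write_dataset(res$dataset, file.path(out, "annual"))

  # --- fit ---
  res$fit <- stage("fit", {
    priors <- default_priors(res$dataset$grid)
    if (!is.null(config$priors))
      priors <- utils::modifyList(priors, config$priors)
    mc_args <- if (is.null(config$mcmc)) list() else config$mcmc
    if (is.null(mc_args$seed)) mc_args$seed <- seed
    fit_geostat(res$dataset, priors, do.call(mcmc_config, mc_args))
  })
  write_draws(res$fit, file.path(out, "posterior_draws.csv"))

  # --- diagnose ---
  res$diagnostics <- stage("diagnose", diagnose(res$fit, res$dataset))
  utils::write.csv(res$diagnostics$parameters,
                   file.path(out, "diagnostics.csv"), row.names = FALSE)
  utils::write.csv(res$diagnostics$bayes_p,
                   file.path(out, "bayes_p_values.csv"), row.names = FALSE)

  # --- trend ---
  res$trend <- stage("trend", trend_table(res$fit))
  utils::write.csv(res$trend, file.path(out, "trend_table.csv"),
                   row.names = FALSE)

  # --- project + minimum-count update ---
  ab <- utils::modifyList(list(mean = 66, sd = 33, year = 2015),
                          if (is.null(config$abundance)) list() else
                            config$abundance)
  if (ab$year %in% res$fit$years && ab$year < max(res$fit$years)) {
    res$trajectories <- stage("project", {
      prior <- lognormal_from_moments(ab$mean, ab$sd)
      lam <- lambda_streams(res$fit, from = ab$year)
      project_abundance(prior, lam, start_year = ab$year, seed = seed)
    })
    res$abundance_pre <- abundance_table(res$trajectories)
    if (length(config$minimums)) {
      mins <- unlist(config$minimums)
      res$trajectories <- stage("update",
                                apply_minimum_counts(res$trajectories, mins))
      res$abundance_post <- abundance_table(res$trajectories)
      res$trend_updated <- stage("update",
                                 updated_trend_table(res$fit, res$trajectories))
      utils::write.csv(res$trend_updated,
                       file.path(out, "trend_table_updated.csv"),
                       row.names = FALSE)
    }
    abt <- res$abundance_pre
    abt$stage <- "pre-update"
    if (!is.null(res$abundance_post)) {
      post <- res$abundance_post
      post$stage <- "post-update"
      abt <- rbind(abt, post)
    }
    utils::write.csv(abt, file.path(out, "abundance_summary.csv"),
                     row.names = FALSE)
  }

  meta <- list(
    package_version = as.character(utils::packageVersion("vaquitrend")),
    r_version = R.version.string,
    seed = seed,
    mcmc = unclass(res$fit$config),
    fingerprint = res$fit$fingerprint,
    convergence_passed = isTRUE(res$fit$convergence$passed),
    minimums = as.list(config$minimums),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(meta, file.path(out, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  res$paths <- list.files(out, full.names = TRUE)
  if (!isTRUE(res$fit$convergence$passed))
    warning("pipeline completed but the convergence screen flagged the fit",
            call. = FALSE)
  invisible(res)
}

#' Serialize posterior draws to CSV
#'
#' One row per retained draw; columns for every annual mean, every spatial
#' effect (Z_year_site), the variance components and the range parameter.
#'
#' @param draws a `geostat_draws` fit.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_draws <- function(draws, path) {
  Zc <- do.call(cbind, lapply(seq_along(draws$years), function(t) {
    m <- draws$Z[, t, , drop = TRUE]
    colnames(m) <- paste0("Z_", draws$years[t], "_", draws$sites)
    m
  }))
  df <- data.frame(draws$mu, Zc,
                   sigma2_eps = draws$sigma2_eps,
                   sigma2_z = draws$sigma2_z,
                   rho = draws$rho, check.names = FALSE)
  names(df)[seq_along(draws$years)] <- paste0("mu_", draws$years)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
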
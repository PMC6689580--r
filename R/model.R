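#' Log transform of mean daily click counts
#'
#' The trend model works on Y = log(W + 1), which maps a mean of zero clicks
#' per day to exactly zero and stabilizes the heavy right tail of click
#' counts.
#'
#' @param W nonnegative mean clicks per day.
#' @return natural log of (W + 1).
#' @export
log_transform <- function(W) {
  if (any(W < 0, na.rm = TRUE))
    stop("W must be nonnegative", call. = FALSE)
  log1p(W)
}

#' Exponential spatial correlation matrix
#'
#' Entry (i, j) is exp(-3 h_ij / rho), where h_ij is the Euclidean distance
#' in kilometres between sites i and j. With this parameterization the
#' correlation has dropped to exp(-3) (about 0.05) at distance rho, so rho is
#' the "practical range" of the spatial smoothness.
#'
#' @param grid a [site_grid()] (or a precomputed distance matrix).
#' @param rho practical range in kilometres, strictly positive.
#' @return site-by-site correlation matrix with unit diagonal.
#' @export
exp_correlation <- function(grid, rho) {
  if (rho <= 0) stop("rho must be strictly positive", call. = FALSE)
  h <- if (is.matrix(grid)) grid else site_distances(grid)
  if (any(h[upper.tri(h)] == 0))
    warning("duplicated site coordinates: correlation matrix is singular ",
            "in the pure-spatial limit", call. = FALSE)
  R <- exp(-3 * h / rho)
  diag(R) <- 1
  R
}

#' Default prior specification
#'
#' Diffuse priors for the geostatistical trend model: Normal(0, variance
#' `mu_var`) on each annual mean mu_t; Inverse-Gamma(shape, rate) on the
#' observation variance sigma2_eps and the spatial variance sigma2_z; Uniform
#' on the practical range rho between `rho_min` and four times the maximum
#' inter-site distance. Every element can be overridden, so a fit can be
#' matched to any fully specified prior set.
#'
#' @param grid a [site_grid()] (used to scale the rho prior).
#' @param ... overrides for individual elements.
#' @return named list of prior hyperparameters.
#' @export
default_priors <- function(grid, ...) {
  hmax <- max(site_distances(grid))
  pr <- list(mu_mean = 0, mu_var = 1e3,
             eps_shape = 0.001, eps_rate = 0.001,
             z_shape = 0.001, z_rate = 0.001,
             # floor keeps the range prior proper on degenerate grids
             rho_min = 0.01, rho_max = max(4 * hmax, 10))
  utils::modifyList(pr, list(...))
}

#' Widen a prior specification by a common factor
#'
#' Multiplies every prior scale by `factor`: the mu variance by factor^2, the
#' inverse-gamma shapes and rates down by factor (flatter), and the rho upper
#' bound up by factor. Used for prior-sensitivity reruns.
#'
#' @param priors a prior list from [default_priors()].
#' @param factor widening factor >= 1.
#' @return widened prior list.
#' @export
widen_priors <- function(priors, factor) {
  stopifnot(factor > 0)
  priors$mu_var <- priors$mu_var * factor^2
  priors$eps_shape <- priors$eps_shape / factor
  priors$eps_rate <- priors$eps_rate / factor
  priors$z_shape <- priors$z_shape / factor
  priors$z_rate <- priors$z_rate / factor
  priors$rho_max <- priors$rho_max * factor
  priors
}

#' MCMC configuration
#'
#' Defaults mirror the monitoring analysis this package was built around: a
#' single chain, 7500 burn-in iterations, and 10 000 retained draws taken as
#' every 100th post-burn-in sample.
#'
#' @param n_burn burn-in iterations discarded.
#' @param n_keep retained draws after thinning.
#' @param thin thinning interval (>= 1).
#' @param seed RNG seed; the full draw sequence is reproducible from it.
#' @param init `"default"` (data-based starting values), `"random"`, or a
#'   named list giving explicit starting values for any of `mu`, `Z`,
#'   `sigma2_eps`, `sigma2_z`, `rho`.
#' @param jitter diagonal jitter added to the spatial correlation matrix
#'   before factorization, for numerical stability.
#' @return list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_burn = 7500, n_keep = 10000, thin = 100,
                        seed = 1L, init = "default", jitter = 1e-10) {
  stopifnot(n_burn >= 0, n_keep > 0, thin >= 1)
  structure(list(n_burn = as.integer(n_burn), n_keep = as.integer(n_keep),
                 thin = as.integer(thin), seed = as.integer(seed),
                 init = init, jitter = jitter),
            class = "mcmc_config")
}

# Internal: lay out a monitoring_dataset as Y and n matrices (years x sites),
# NA / 0 marking site-years without data.
dataset_matrices <- function(dataset) {
  s <- dataset$summaries
  years <- sort(unique(s$year))
  sites <- dataset$grid$site_id
  Y <- matrix(NA_real_, length(years), length(sites),
              dimnames = list(years, sites))
  n <- matrix(0, length(years), length(sites),
              dimnames = list(years, sites))
  ti <- cbind(match(s$year, years), match(s$site_id, sites))
  Y[ti] <- log_transform(s$W)
  n[ti] <- s$n
  list(Y = Y, n = n, years = years, sites = sites)
}

inv_gamma_logd <- function(x, shape, rate) {
  shape * log(rate) - lgamma(shape) - (shape + 1) * log(x) - rate / x
}

#' Log posterior density of the geostatistical trend model
#'
#' Sum of (i) the Normal log-likelihood of each observed log-scale site-year
#' mean Y_ti with mean mu_t + Z_ti and variance sigma2_eps / n_ti, (ii) the
#' multivariate-normal log-density of each year's spatial effect vector Z_t
#' under covariance sigma2_z * R(rho), and (iii) the log-priors. Up to a
#' constant this is the target the sampler explores; it is exported so that
#' fits can be cross-checked against quadrature or closed forms on small
#' problems.
#'
#' @param params list with elements `mu` (one per year), `Z` (years x sites
#'   matrix), `sigma2_eps`, `sigma2_z`, `rho`.
#' @param dataset a `monitoring_dataset`.
#' @param priors a prior list, see [default_priors()].
#' @return the log posterior density (unnormalized); `-Inf` outside the
#'   parameter space.
#' @export
log_posterior <- function(params, dataset, priors = default_priors(dataset$grid)) {
  m <- dataset_matrices(dataset)
  mu <- params$mu
  Z <- params$Z
  if (length(mu) != length(m$years) || !all(dim(Z) == dim(m$Y)))
    stop("params have wrong dimensions for this dataset", call. = FALSE)
  if (params$sigma2_eps <= 0 || params$sigma2_z <= 0 ||
      params$rho < priors$rho_min || params$rho > priors$rho_max)
    return(-Inf)
  obs <- !is.na(m$Y)
  mean_mat <- sweep(Z, 1, mu, `+`)
  sd_mat <- sqrt(params$sigma2_eps / ifelse(m$n > 0, m$n, 1))
  ll <- sum(stats::dnorm(m$Y[obs], mean_mat[obs], sd_mat[obs], log = TRUE))
  R <- exp_correlation(dataset$grid, params$rho)
  U <- chol(R + diag(1e-10, nrow(R)))
  logdetR <- 2 * sum(log(diag(U)))
  S <- nrow(R)
  lz <- 0
  for (t in seq_along(mu)) {
    w <- backsolve(U, Z[t, ], transpose = TRUE)
    lz <- lz - 0.5 * (S * log(2 * pi * params$sigma2_z) + logdetR +
                        sum(w^2) / params$sigma2_z)
  }
  lp <- sum(stats::dnorm(mu, priors$mu_mean, sqrt(priors$mu_var), log = TRUE)) +
    inv_gamma_logd(params$sigma2_eps, priors$eps_shape, priors$eps_rate) +
    inv_gamma_logd(params$sigma2_z, priors$z_shape, priors$z_rate) -
    log(priors$rho_max - priors$rho_min)
  ll + lz + lp
}

#' Fit the Bayesian geostatistical trend model
#'
#' Metropolis-within-Gibbs sampler for the hierarchical model
#' \deqn{Y_{ti} \sim N(\mu_t + Z_{ti},\; \sigma^2_\epsilon / n_{ti}), \quad
#'       Z_t \sim MVN(0,\; \sigma^2_z R(\rho)),}
#' with R(rho) the exponential correlation of [exp_correlation()]. Updates:
#' the variance parameters (log sigma2_eps, log sigma2_z, log rho) move by a
#' joint random-walk Metropolis step evaluated against the *marginal*
#' likelihood with (mu, Z) integrated out analytically (a collapsed update;
#' conditioning on the latent field couples the variances to it so tightly
#' that conditional updates take tens of thousands of iterations to relax),
#' with the step size adapted during burn-in only; then each year's
#' (mu_t, Z_t) is drawn jointly from its exact multivariate-normal full
#' conditional given the variances (sites without data that year receive Z
#' from the spatial conditional prior given the observed sites, which is how
#' the model borrows strength across the grid).
#'
#' @param dataset a `monitoring_dataset` spanning at least one year (two for
#'   any trend to be estimable).
#' @param priors prior list, see [default_priors()].
#' @param config an [mcmc_config()].
#' @param fix optional named list pinning any of `sigma2_eps`, `sigma2_z`,
#'   `rho` at fixed values (no update is performed for a pinned parameter);
#'   used for validation against closed-form Gaussian posteriors.
#' @param diagnose_fit run a Geweke convergence screen on the retained chains
#'   and store the result (default TRUE; a flagged fit warns but is still
#'   returned).
#' @return object of class `geostat_draws`: list with `mu` (draws x years),
#'   `Z` (draws x years x sites), `sigma2_eps`, `sigma2_z`, `rho` (vectors),
#'   `years`, `sites`, `accept` (Metropolis acceptance rates), `config`,
#'   `priors`, `convergence` (Geweke screen), `fingerprint`.
#' @export
fit_geostat <- function(dataset, priors = default_priors(dataset$grid),
                        config = mcmc_config(), fix = list(),
                        diagnose_fit = TRUE) {
  m <- dataset_matrices(dataset)
  Y <- m$Y; n <- m$n
  T_ <- length(m$years); S <- length(m$sites)
  if (T_ < 1) stop("dataset spans no years", call. = FALSE)
  obs <- !is.na(Y)
  H <- site_distances(dataset$grid)

  set.seed(config$seed)

  # starting values
  mu <- vapply(seq_len(T_), function(t) {
    if (any(obs[t, ])) mean(Y[t, obs[t, ]]) else 0
  }, 0)
  Z <- matrix(0, T_, S)
  s2e <- if (!is.null(fix$sigma2_eps)) fix$sigma2_eps else {
    v <- stats::var(Y[obs] - mu[row(Y)[obs]]) * mean(n[obs])
    max(v, 0.1)
  }
  s2z <- if (!is.null(fix$sigma2_z)) fix$sigma2_z else
    max(stats::var(Y[obs] - mu[row(Y)[obs]]) / 2, 0.05)
  rho <- if (!is.null(fix$rho)) fix$rho else
    min(max(max(H) / 3, priors$rho_min * 1.01), priors$rho_max * 0.99)
  if (identical(config$init, "random")) {
    mu <- mu + stats::rnorm(T_, 0, 0.5)
    if (is.null(fix$sigma2_eps)) s2e <- s2e * exp(stats::rnorm(1, 0, 0.5))
    if (is.null(fix$sigma2_z)) s2z <- s2z * exp(stats::rnorm(1, 0, 0.5))
    if (is.null(fix$rho))
      rho <- min(max(rho * exp(stats::rnorm(1, 0, 0.5)),
                     priors$rho_min), priors$rho_max)
  } else if (is.list(config$init)) {
    init <- config$init
    if (!is.null(init$mu)) mu <- init$mu
    if (!is.null(init$Z)) Z <- init$Z
    if (!is.null(init$sigma2_eps) && is.null(fix$sigma2_eps)) s2e <- init$sigma2_eps
    if (!is.null(init$sigma2_z) && is.null(fix$sigma2_z)) s2z <- init$sigma2_z
    if (!is.null(init$rho) && is.null(fix$rho)) rho <- init$rho
  }

  spatial_chol <- function(rho) {
    R <- exp(-3 * H / rho)
    diag(R) <- 1 + config$jitter
    U <- chol(R)
    list(R = R, U = U, Rinv = chol2inv(U), logdet = 2 * sum(log(diag(U))))
  }
  sp <- spatial_chol(rho)

  # marginal log-likelihood of the observed Y with (mu, Z) integrated out:
  # per year, Y_o ~ MVN(mu_mean, mu_var J + s2z R[o,o] + s2e diag(1/n_o))
  obs_idx <- lapply(seq_len(T_), function(t) which(obs[t, ]))
  marginal_ll <- function(s2e, s2z, R) {
    ll <- 0
    for (t in seq_len(T_)) {
      o <- obs_idx[[t]]
      if (length(o) == 0) next
      Sig <- priors$mu_var + s2z * R[o, o, drop = FALSE]
      diag(Sig) <- diag(Sig) + s2e / n[t, o] + config$jitter
      U <- tryCatch(chol(Sig), error = function(e) NULL)
      if (is.null(U)) return(-Inf)
      w <- backsolve(U, Y[t, o] - priors$mu_mean, transpose = TRUE)
      ll <- ll - sum(log(diag(U))) - 0.5 * sum(w^2) -
        0.5 * length(o) * log(2 * pi)
    }
    ll
  }

  n_iter <- config$n_burn + config$n_keep * config$thin
  keep_mu <- matrix(NA_real_, config$n_keep, T_,
                    dimnames = list(NULL, m$years))
  keep_Z <- array(NA_real_, c(config$n_keep, T_, S),
                  dimnames = list(NULL, m$years, m$sites))
  keep_s2e <- keep_s2z <- keep_rho <- numeric(config$n_keep)

  free <- c(sigma2_eps = is.null(fix$sigma2_eps),
            sigma2_z = is.null(fix$sigma2_z),
            rho = is.null(fix$rho))
  n_obs_total <- sum(obs)
  Y0 <- ifelse(obs, Y, 0)

  var_log_target <- function(s2e, s2z, rho, R) {
    marginal_ll(s2e, s2z, R) +
      inv_gamma_logd(s2e, priors$eps_shape, priors$eps_rate) +
      inv_gamma_logd(s2z, priors$z_shape, priors$z_rate) +
      log(s2e) + log(s2z) + log(rho)   # Jacobians of the log-scale walk
  }
  lt_cur <- var_log_target(s2e, s2z, rho, sp$R)

  # adaptive-Metropolis machinery (burn-in only): scalar step times a
  # proposal covariance learned from the burn-in history of the log
  # variance parameters, so proposals follow the sigma2_eps/sigma2_z ridge
  step_v <- 0.3
  prop_U <- diag(3)
  burn_hist <- if (config$n_burn > 0) matrix(NA_real_, config$n_burn, 3)
  acc_v <- try_v <- 0L
  tot_acc_v <- tot_try_v <- 0L

  stored <- 0L
  for (iter in seq_len(n_iter)) {
    # --- collapsed joint RW-Metropolis on the free variance parameters ---
    if (any(free)) {
      try_v <- try_v + 1L
      tot_try_v <- tot_try_v + 1L
      jump <- drop(stats::rnorm(3) %*% prop_U) * step_v * free
      s2e_p <- s2e * exp(jump[1])
      s2z_p <- s2z * exp(jump[2])
      rho_p <- rho * exp(jump[3])
      if (rho_p >= priors$rho_min && rho_p <= priors$rho_max) {
        sp_p <- if (free[["rho"]] && jump[3] != 0) spatial_chol(rho_p) else sp
        lt_prop <- var_log_target(s2e_p, s2z_p, rho_p, sp_p$R)
        if (log(stats::runif(1)) < lt_prop - lt_cur) {
          s2e <- s2e_p; s2z <- s2z_p; rho <- rho_p
          sp <- sp_p
          lt_cur <- lt_prop
          acc_v <- acc_v + 1L
          tot_acc_v <- tot_acc_v + 1L
        }
      }
      if (iter <= config$n_burn) {
        burn_hist[iter, ] <- log(c(s2e, s2z, rho))
        if (iter %% 50 == 0) {
          step_v <- min(max(step_v * exp(acc_v / try_v - 0.3), 1e-3), 10)
          acc_v <- try_v <- 0L
        }
        if (iter %% 200 == 0 && iter >= 400) {
          C <- stats::cov(burn_hist[seq_len(iter), , drop = FALSE])
          C <- C + diag(1e-6, 3)
          U <- tryCatch(chol(C), error = function(e) NULL)
          if (!is.null(U)) {
            # normalize so step_v keeps its meaning as an overall scale
            prop_U <- U / exp(mean(log(diag(U)[free])))
          }
        }
      }
    }

    # --- joint (mu_t, Z_t) Gibbs draw, year by year ---
    Qz <- sp$Rinv / s2z
    for (t in seq_len(T_)) {
      d <- n[t, ] / s2e                        # zero where no data
      P <- matrix(0, S + 1, S + 1)
      P[1, 1] <- 1 / priors$mu_var + sum(d)
      P[1, -1] <- d
      P[-1, 1] <- d
      P[-1, -1] <- Qz
      diag(P)[-1] <- diag(Qz) + d
      b <- c(priors$mu_mean / priors$mu_var + sum(d * Y0[t, ]), d * Y0[t, ])
      U <- chol(P)
      mean_t <- backsolve(U, backsolve(U, b, transpose = TRUE))
      theta <- mean_t + backsolve(U, stats::rnorm(S + 1))
      mu[t] <- theta[1]
      Z[t, ] <- theta[-1]
    }

    if (iter > config$n_burn && (iter - config$n_burn) %% config$thin == 0) {
      stored <- stored + 1L
      keep_mu[stored, ] <- mu
      keep_Z[stored, , ] <- Z
      keep_s2e[stored] <- s2e
      keep_s2z[stored] <- s2z
      keep_rho[stored] <- rho
    }
  }

  fit <- structure(list(
    mu = keep_mu, Z = keep_Z,
    sigma2_eps = keep_s2e, sigma2_z = keep_s2z, rho = keep_rho,
    years = m$years, sites = m$sites,
    accept = c(variances = if (tot_try_v > 0) tot_acc_v / tot_try_v else NA),
    config = config, priors = priors, fix = fix,
    fingerprint = sprintf("T%d_S%d_obs%d_sumY%.6g_sumn%d",
                          T_, S, n_obs_total, sum(Y0), sum(n))
  ), class = "geostat_draws")

  if (diagnose_fit && config$n_keep >= 100) {
    fit$convergence <- convergence_screen(fit)
    if (!fit$convergence$passed)
      warning("Geweke convergence screen flagged parameter(s): ",
              paste(fit$convergence$flagged, collapse = ", "),
              "; inspect diagnostics before using this fit", call. = FALSE)
  }
  fit
}

#' @export
print.geostat_draws <- function(x, ...) {
  cat(sprintf("Geostatistical trend fit: %d retained draws, %d years x %d sites\n",
              length(x$sigma2_eps), length(x$years), length(x$sites)))
  cat(sprintf("Posterior means: sigma2_eps = %.3g, sigma2_z = %.3g, rho = %.3g km\n",
              mean(x$sigma2_eps), mean(x$sigma2_z), mean(x$rho)))
  if (!is.null(x$convergence))
    cat("Convergence screen:",
        if (x$convergence$passed) "passed" else
          paste("FLAGGED:", paste(x$convergence$flagged, collapse = ", ")),
        "\n")
  invisible(x)
}

#' Prior-sensitivity rerun
#'
#' Refits the model with every prior scale widened by `widen_factor` and
#' reports the largest absolute difference in posterior-mean annual change
#' ratios (lambda) between the baseline and the widened fit. Small
#' differences indicate the data, not the priors, drive the trend estimates.
#'
#' @param dataset a `monitoring_dataset`.
#' @param priors baseline prior list.
#' @param config an [mcmc_config()]; the same seed is used for both fits.
#' @param widen_factor factor applied by [widen_priors()].
#' @param baseline optional already-computed baseline `geostat_draws`.
#' @return list with both fits, the per-pair posterior-mean lambdas, and
#'   `max_abs_diff`.
#' @export
rerun_with_wider_priors <- function(dataset, priors = default_priors(dataset$grid),
                                    config = mcmc_config(),
                                    widen_factor = 10, baseline = NULL) {
  if (is.null(baseline))
    baseline <- fit_geostat(dataset, priors, config, diagnose_fit = FALSE)
  wide <- fit_geostat(dataset, widen_priors(priors, widen_factor), config,
                      diagnose_fit = FALSE)
  lam <- function(fit) {
    B <- compute_B(fit)
    vapply(seq_len(ncol(B) - 1), function(t) mean(B[, t + 1] / B[, t]), 0)
  }
  l0 <- lam(baseline); l1 <- lam(wide)
  list(baseline = baseline, widened = wide,
       lambda_baseline = l0, lambda_widened = l1,
       max_abs_diff = max(abs(l1 - l0)))
}
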
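#' Spectral density of a chain at frequency zero
#'
#' Lag-window estimate of the long-run variance (2*pi times the spectral
#' density at zero) of a stationary chain, used by both the Geweke and the
#' Heidelberger-Welch diagnostics. A Tukey-Hanning lag window of half-width
#' `max_lag` is applied to the empirical autocovariances; the default
#' truncation rule `max_lag = floor(sqrt(n))` grows slowly with chain
#' length, a bias/variance compromise that keeps the resulting test
#' statistics close to their nominal null distributions for both white and
#' moderately autocorrelated chains.
#'
#' @param x numeric chain.
#' @param max_lag lag-window truncation point.
#' @return long-run variance estimate (per observation); dividing by
#'   `length(x)` gives the variance of the chain mean.
#' @export
spectrum0 <- function(x, max_lag = floor(sqrt(length(x)))) {
  n <- length(x)
  if (n < 10) stop("chain too short for spectral estimation", call. = FALSE)
  if (stats::var(x) == 0)
    stop("zero-variance chain: spectral density undefined", call. = FALSE)
  max_lag <- min(max_lag, n - 1)
  ac <- stats::acf(x, lag.max = max_lag, type = "covariance",
                   plot = FALSE, demean = TRUE)$acf[, 1, 1]
  w <- 0.5 * (1 + cos(pi * seq_len(max_lag) / max_lag))
  s0 <- ac[1] + 2 * sum(w * ac[-1])
  max(s0, .Machine$double.eps * ac[1])
}

#' Geweke convergence diagnostic
#'
#' Compares the mean of an early segment of a chain with the mean of a late
#' segment, standardized by spectral estimates of each segment's long-run
#' variance. Under stationarity the statistic is asymptotically standard
#' normal; |z| well above 2-3 indicates the chain had not converged.
#'
#' @param chain numeric vector of MCMC draws (length >= 100).
#' @param frac_a fraction of the chain in the early segment (default 0.1).
#' @param frac_b fraction in the late segment (default 0.5).
#' @return the z-score (scalar).
#' @export
geweke_z <- function(chain, frac_a = 0.1, frac_b = 0.5) {
  n <- length(chain)
  if (n < 100) stop("chain length must be >= 100", call. = FALSE)
  stopifnot(frac_a > 0, frac_b > 0, frac_a + frac_b <= 1)
  if (stats::var(chain) == 0)
    stop("zero-variance chain: Geweke statistic undefined", call. = FALSE)
  na <- floor(frac_a * n)
  nb <- floor(frac_b * n)
  a <- chain[seq_len(na)]
  b <- chain[seq.int(n - nb + 1L, n)]
  (mean(a) - mean(b)) / sqrt(spectrum0(a) / na + spectrum0(b) / nb)
}

# Asymptotic CDF of the Cramer-von Mises statistic (Csorgo-Faraway series).
pcramer_cvm <- function(q) {
  vapply(q, function(qi) {
    if (qi <= 0) return(0)
    total <- 0
    for (k in 0:3) {
      u <- (4 * k + 1)^2 / (16 * qi)
      if (u > 700) next
      total <- total +
        (gamma(k + 0.5) * sqrt(4 * k + 1)) /
        (gamma(k + 1) * pi^1.5 * sqrt(qi)) *
        exp(-u) * besselK(u, 0.25)
    }
    min(max(total, 0), 1)
  }, 0)
}

#' Heidelberger-Welch stationarity and halfwidth diagnostic
#'
#' Stationarity: a Cramer-von Mises test on the Brownian-bridge transform of
#' the cumulative sums, applied first to the full chain and then, while the
#' test rejects, to the chain with successive initial 10% increments removed,
#' up to half the chain. Halfwidth: on the retained portion, the
#' (1 - alpha) confidence halfwidth of the chain mean (from the long-run
#' variance) must be below `halfwidth_eps` times |mean|. The halfwidth test
#' is relative, so for chains whose mean is near zero it is flagged
#' unreliable rather than failed.
#'
#' @param chain numeric vector of MCMC draws (length >= 100).
#' @param alpha significance level for both parts (default 0.05).
#' @param halfwidth_eps relative halfwidth tolerance (default 0.1).
#' @return list: `stationarity` (logical), `start_frac` (fraction discarded
#'   before stationarity was accepted, NA if never), `halfwidth` (logical or
#'   NA when unreliable), `halfwidth_rel`, `mean`, `cvm_pvalue`.
#' @export
heidelberger_welch <- function(chain, alpha = 0.05, halfwidth_eps = 0.1) {
  n <- length(chain)
  if (n < 100) stop("chain length must be >= 100", call. = FALSE)
  if (stats::var(chain) == 0)
    stop("zero-variance chain: diagnostic undefined", call. = FALSE)
  stationary <- FALSE
  start_frac <- NA_real_
  pval <- NA_real_
  for (f in seq(0, 0.5, by = 0.1)) {
    x <- chain[seq.int(floor(f * n) + 1L, n)]
    nx <- length(x)
    s0 <- spectrum0(x)
    cs <- cumsum(x)
    k <- seq_len(nx)
    bridge <- (cs - k * mean(x)) / sqrt(nx * s0)
    cvm <- sum(bridge^2) / nx
    pval <- 1 - pcramer_cvm(cvm)
    if (pval > alpha) {
      stationary <- TRUE
      start_frac <- f
      break
    }
  }
  if (!stationary) {
    return(list(stationarity = FALSE, start_frac = NA_real_,
                halfwidth = NA, halfwidth_rel = NA_real_,
                mean = mean(chain), cvm_pvalue = pval))
  }
  x <- chain[seq.int(floor(start_frac * n) + 1L, n)]
  m <- mean(x)
  hw <- stats::qnorm(1 - alpha / 2) * sqrt(spectrum0(x) / length(x))
  rel <- hw / abs(m)
  # a mean statistically indistinguishable from zero makes the relative
  # halfwidth criterion meaningless, so it is flagged rather than failed
  near_zero <- abs(m) < hw
  list(stationarity = TRUE, start_frac = start_frac,
       halfwidth = if (near_zero) NA else rel < halfwidth_eps,
       halfwidth_rel = if (near_zero) NA_real_ else rel,
       mean = m, cvm_pvalue = pval)
}

#' Posterior predictive p-values per observed site-year
#'
#' For each observed site-year, the posterior predictive probability that a
#' replicate log-scale observation falls at or below the one actually seen:
#' p_ti = E_post[ Phi( (Y_ti - mu_t - Z_ti) / sqrt(sigma2_eps / n_ti) ) ],
#' averaged over the retained draws. This is the expectation of the
#' indicator-based check (replicate <= observed) and is deterministic given
#' the draws. Values piling up near 0 or 1 indicate systematic misfit; under
#' a well-specified model the p-values are approximately uniform.
#'
#' @param draws a `geostat_draws` fit.
#' @param dataset the `monitoring_dataset` the fit was run on.
#' @return data frame `year`, `site_id`, `p`.
#' @export
bayes_p_values <- function(draws, dataset) {
  m <- dataset_matrices(dataset)
  if (!identical(m$years, draws$years) || !identical(m$sites, draws$sites))
    stop("draws and dataset do not cover the same years/sites", call. = FALSE)
  obs <- which(!is.na(m$Y), arr.ind = TRUE)
  p <- vapply(seq_len(nrow(obs)), function(k) {
    t <- obs[k, 1]; i <- obs[k, 2]
    mean(stats::pnorm(m$Y[t, i], draws$mu[, t] + draws$Z[, t, i],
                      sqrt(draws$sigma2_eps / m$n[t, i])))
  }, 0)
  data.frame(year = m$years[obs[, 1]], site_id = m$sites[obs[, 2]], p = p,
             stringsAsFactors = FALSE)
}

# Internal: monitored scalar chains of a fit, as a named list.
monitored_chains <- function(draws) {
  ch <- c(
    stats::setNames(lapply(seq_along(draws$years),
                           function(t) draws$mu[, t]),
                    paste0("mu_", draws$years)),
    list(sigma2_z = draws$sigma2_z, rho = draws$rho)
  )
  if (is.null(draws$fix$sigma2_eps))
    ch$sigma2_eps <- draws$sigma2_eps
  ch <- Filter(function(x) stats::var(x) > 0, ch)
  ch
}

# Internal: quick Geweke screen used by fit_geostat.
convergence_screen <- function(draws, z_limit = 3) {
  ch <- monitored_chains(draws)
  z <- vapply(ch, geweke_z, 0)
  flagged <- names(z)[abs(z) > z_limit]
  list(passed = length(flagged) == 0, geweke_z = z, flagged = flagged)
}

#' Full diagnostic report for a fit
#'
#' Geweke z-scores and Heidelberger-Welch stationarity/halfwidth results for
#' every monitored parameter chain (annual means, variance components,
#' spatial range), plus posterior predictive p-values per observed site-year
#' when the dataset is supplied.
#'
#' @param draws a `geostat_draws` fit.
#' @param dataset optional `monitoring_dataset` for predictive checks.
#' @param alpha,halfwidth_eps passed to [heidelberger_welch()].
#' @return object of class `diagnostic_report`: list with `parameters` (data
#'   frame of per-parameter results) and `bayes_p` (data frame or NULL).
#' @export
diagnose <- function(draws, dataset = NULL, alpha = 0.05,
                     halfwidth_eps = 0.1) {
  ch <- monitored_chains(draws)
  rows <- lapply(names(ch), function(nm) {
    hw <- heidelberger_welch(ch[[nm]], alpha, halfwidth_eps)
    data.frame(parameter = nm,
               geweke_z = geweke_z(ch[[nm]]),
               hw_stationarity = hw$stationarity,
               hw_halfwidth = if (is.na(hw$halfwidth)) NA else hw$halfwidth,
               posterior_mean = mean(ch[[nm]]),
               stringsAsFactors = FALSE)
  })
  rep <- list(parameters = do.call(rbind, rows),
              bayes_p = if (!is.null(dataset)) bayes_p_values(draws, dataset))
  class(rep) <- "diagnostic_report"
  rep
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat("MCMC diagnostic report\n")
  print(x$parameters, row.names = FALSE, digits = 3)
  if (!is.null(x$bayes_p)) {
    extreme <- mean(x$bayes_p$p < 0.025 | x$bayes_p$p > 0.975)
    cat(sprintf(
      "Posterior predictive checks: %d site-years, %.1f%% outside (0.025, 0.975)\n",
      nrow(x$bayes_p), 100 * extreme))
  }
  invisible(x)
}
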
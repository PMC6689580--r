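#' Lognormal abundance distribution from arithmetic moments
#'
#' Represents an abundance estimate reported as an arithmetic mean and
#' standard deviation (animals) by the moment-matched lognormal: log-scale
#' variance sigma^2 = ln(1 + (sd/mean)^2) and location mu = ln(mean) -
#' sigma^2 / 2, so that the back-transformed arithmetic mean and sd
#' reproduce the inputs exactly. The distribution's median is exp(mu).
#'
#' @param mean arithmetic mean, > 0.
#' @param sd arithmetic standard deviation, > 0.
#' @return object of class `abundance_prior`: list with `mean`, `sd`,
#'   `meanlog`, `sdlog`, `median`.
#' @examples
#' p <- lognormal_from_moments(66, 33)
#' p$median   # about 59 animals
#' @export
lognormal_from_moments <- function(mean, sd) {
  if (mean <= 0 || sd <= 0)
    stop("mean and sd must be strictly positive", call. = FALSE)
  s2 <- log(1 + (sd / mean)^2)
  ml <- log(mean) - s2 / 2
  structure(list(mean = mean, sd = sd, meanlog = ml, sdlog = sqrt(s2),
                 median = exp(ml)),
            class = "abundance_prior")
}

#' @export
print.abundance_prior <- function(x, ...) {
  cat(sprintf(
    "Lognormal abundance prior: mean %.1f, sd %.1f (median %.1f animals)\n",
    x$mean, x$sd, x$median))
  invisible(x)
}

#' Draw from an abundance prior
#'
#' @param prior an `abundance_prior`.
#' @param n number of draws.
#' @return numeric vector of abundance draws.
#' @export
sample_abundance <- function(prior, n) {
  stats::rlnorm(n, prior$meanlog, prior$sdlog)
}

#' Project abundance trajectories along posterior trend draws
#'
#' Pairs the i-th draw from the abundance prior with the i-th joint lambda
#' draw and multiplies in succession:
#' N_{t+1} = N_t * lambda_{t,t+1} per trajectory, exactly. Pairing is by
#' index, so the between-year posterior correlation of the lambda draws is
#' preserved; the prior draw is independent of the lambda draws, as the
#' abundance estimate comes from an independent survey.
#'
#' @param prior an [lognormal_from_moments()] abundance prior.
#' @param lambda matrix of lambda draws (rows = trajectories, columns =
#'   successive transitions, e.g. from [lambda_streams()]).
#' @param start_year calendar year of the prior estimate.
#' @param n_trajectories number of trajectories; must not exceed the number
#'   of lambda draws available (defaults to all of them).
#' @param seed RNG seed for the prior draws.
#' @return object of class `trajectory_set`: list with `N` (matrix
#'   trajectories x years), `lambda` (the paired draws used), `years`,
#'   `retained` (logical, all TRUE before any update), `minimums` (empty).
#' @export
project_abundance <- function(prior, lambda, start_year,
                              n_trajectories = nrow(lambda), seed = 1L) {
  lambda <- as.matrix(lambda)
  if (n_trajectories > nrow(lambda))
    stop("n_trajectories exceeds the number of lambda draws (",
         nrow(lambda), ")", call. = FALSE)
  lambda <- lambda[seq_len(n_trajectories), , drop = FALSE]
  set.seed(seed)
  N0 <- sample_abundance(prior, n_trajectories)
  k <- ncol(lambda)
  years <- start_year + 0:k
  N <- matrix(NA_real_, n_trajectories, k + 1,
              dimnames = list(NULL, years))
  N[, 1] <- N0
  for (j in seq_len(k)) N[, j + 1] <- N[, j] * lambda[, j]
  structure(list(N = N, lambda = lambda, years = years,
                 retained = rep(TRUE, n_trajectories),
                 minimums = integer(0)),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("Trajectory set: %d trajectories, years %d-%d; %d retained\n",
              nrow(x$N), x$years[1], x$years[length(x$years)],
              sum(x$retained)))
  invisible(x)
}

#' Update trajectories with minimum-known-alive counts
#'
#' A verified minimum count of living animals in a year makes the posterior
#' probability of fewer animals in that year zero. Trajectories whose
#' projected abundance falls below any minimum are discarded (rejection
#' sampling from the truncated posterior); all downstream summaries use the
#' retained set. The comparison is on the continuous projected abundance by
#' default; `rounding` switches to floor or ceiling semantics for
#' sensitivity analysis.
#'
#' @param traj a `trajectory_set`.
#' @param minimums named numeric vector, names = years, values = minimum
#'   number known alive.
#' @param rounding `"none"` (default), `"floor"`, or `"ceiling"`: how the
#'   projected abundance is treated before comparison with the minimum.
#' @return the `trajectory_set` with its `retained` mask updated (masks
#'   compose: already-discarded trajectories stay discarded).
#' @export
apply_minimum_counts <- function(traj, minimums,
                                 rounding = c("none", "floor", "ceiling")) {
  rounding <- match.arg(rounding)
  if (any(minimums < 0)) stop("minimum counts must be nonnegative",
                              call. = FALSE)
  yrs <- names(minimums)
  if (!all(yrs %in% colnames(traj$N)))
    stop("minimum-count years absent from trajectories: ",
         paste(setdiff(yrs, colnames(traj$N)), collapse = ", "),
         call. = FALSE)
  keep <- traj$retained
  for (y in yrs) {
    Ny <- switch(rounding,
                 none = traj$N[, y],
                 floor = floor(traj$N[, y]),
                 ceiling = ceiling(traj$N[, y]))
    keep <- keep & Ny >= minimums[[y]]
  }
  if (!any(keep))
    stop("no trajectories satisfy the minimum counts; ",
         "rerun with more trajectories", call. = FALSE)
  traj$retained <- keep
  traj$minimums <- c(traj$minimums, minimums)
  traj
}

#' Posterior abundance summaries for one year
#'
#' Empirical mean, median and central 95% credible interval of the retained
#' projected abundance in a year, with integer-rounded presentation values
#' alongside the raw ones.
#'
#' @param traj a `trajectory_set`.
#' @param year a year present in the trajectories.
#' @return list: `mean`, `median`, `lower`, `upper` (raw), `rounded`
#'   (named integer vector), `n_retained`.
#' @export
summarize_abundance <- function(traj, year) {
  y <- as.character(year)
  if (!y %in% colnames(traj$N))
    stop("year ", year, " not in trajectories", call. = FALSE)
  x <- traj$N[traj$retained, y]
  if (length(x) == 0) stop("no retained trajectories", call. = FALSE)
  q <- stats::quantile(x, c(0.025, 0.5, 0.975), names = FALSE)
  out <- list(mean = mean(x), median = q[2], lower = q[1], upper = q[3],
              n_retained = length(x))
  out$rounded <- round(c(mean = out$mean, median = out$median,
                         lower = out$lower, upper = out$upper))
  out
}

#' Abundance summary table across years
#'
#' @param traj a `trajectory_set`.
#' @return data frame with one row per projected year: `year`, `mean`,
#'   `median`, `lower`, `upper`, `n_retained`.
#' @export
abundance_table <- function(traj) {
  do.call(rbind, lapply(traj$years, function(y) {
    s <- summarize_abundance(traj, y)
    data.frame(year = y, mean = s$mean, median = s$median,
               lower = s$lower, upper = s$upper,
               n_retained = s$n_retained)
  }))
}

#' Trend table recomputed over retained trajectories
#'
#' The "after incorporation of sightings" counterpart of [trend_table()]:
#' lambda summaries recomputed over the posterior draws whose trajectories
#' survived the minimum-count truncation. Because every lambda within one
#' trajectory comes from a single joint MCMC draw, conditioning on retention
#' propagates to all year pairs, including years before the update.
#'
#' @param draws a `geostat_draws` fit or B matrix (the same draws, in the
#'   same order, that supplied the projection's lambda streams).
#' @param traj the updated `trajectory_set`.
#' @return a `trend_table` data frame.
#' @export
updated_trend_table <- function(draws, traj) {
  B <- if (inherits(draws, "geostat_draws")) compute_B(draws) else draws
  if (nrow(B) < length(traj$retained))
    stop("draws and trajectories are not paired", call. = FALSE)
  retained <- rep(FALSE, nrow(B))
  retained[seq_along(traj$retained)] <- traj$retained
  trend_table(B, retained = retained)
}
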
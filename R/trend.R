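#' Per-draw annual acoustic activity index B_t
#'
#' For each retained draw and each year, the cross-site mean acoustic
#' activity on the click scale:
#' \deqn{B_t = \frac{1}{S}\sum_{i=1}^{S} (\exp(\mu_t + Z_{ti}) - 1),}
#' averaged over all grid sites (including sites without data that year,
#' whose Z was drawn from the spatial conditional prior). B_t can in
#' principle be negative when mu_t + Z_ti < 0 at many sites; draws where
#' that happens are handled downstream by [compute_lambda()].
#'
#' @param draws a `geostat_draws` fit.
#' @return matrix draws x years of B values, colnames the years.
#' @export
compute_B <- function(draws) {
  T_ <- length(draws$years)
  n_draw <- nrow(draws$mu)
  S <- dim(draws$Z)[3]
  B <- vapply(seq_len(T_), function(t) {
    Zt <- draws$Z[, t, , drop = FALSE]
    dim(Zt) <- c(n_draw, S)
    rowMeans(exp(draws$mu[, t] + Zt)) - 1
  }, numeric(n_draw))
  B <- matrix(B, n_draw, T_)   # vapply drops dims for a single draw
  colnames(B) <- draws$years
  B
}

#' Annual change ratio between two years
#'
#' Per-draw ratio lambda = B_t2 / B_t1 for t2 > t1, with posterior mean and
#' central 95% credible interval. Values below 1 indicate a decline;
#' (1 - lambda) * 100 is the percentage decline. Draws in which B_t1 <= 0
#' (possible but pathological on the log scale) are excluded from the ratio
#' and their count reported.
#'
#' @param B matrix of B draws from [compute_B()].
#' @param t1,t2 years (must be column names of `B`), t1 earlier.
#' @param retained optional logical mask over draws (used for the
#'   minimum-count update); default all draws.
#' @return object of class `lambda_summary`: list with `t1`, `t2`, `draws`,
#'   `mean`, `lower`, `upper`, `percent_decline`, `n_excluded`.
#' @export
compute_lambda <- function(B, t1, t2, retained = NULL) {
  c1 <- as.character(t1); c2 <- as.character(t2)
  if (!all(c(c1, c2) %in% colnames(B)))
    stop("years ", t1, " and ", t2, " must both be in the B draws",
         call. = FALSE)
  if (t2 <= t1) stop("t2 must be later than t1", call. = FALSE)
  if (is.null(retained)) retained <- rep(TRUE, nrow(B))
  b1 <- B[retained, c1]
  b2 <- B[retained, c2]
  ok <- b1 > 0
  lam <- b2[ok] / b1[ok]
  q <- stats::quantile(lam, c(0.025, 0.975), names = FALSE)
  structure(list(t1 = t1, t2 = t2, draws = lam,
                 mean = mean(lam), lower = q[1], upper = q[2],
                 percent_decline = (1 - mean(lam)) * 100,
                 n_excluded = sum(!ok)),
            class = "lambda_summary")
}

#' @export
print.lambda_summary <- function(x, ...) {
  cat(sprintf("lambda %d-%d: %.2f (95%% CRI %.2f-%.2f), P(decline) = %.1f%%\n",
              x$t1, x$t2, x$mean, x$lower, x$upper,
              100 * decline_probability(x)))
  if (x$n_excluded > 0)
    cat(sprintf("  (%d draws with non-positive B excluded)\n", x$n_excluded))
  invisible(x)
}

#' Posterior probability of decline
#'
#' Fraction of lambda draws below a threshold: 1.0 for "any decline", 0.8
#' for "declining faster than 20% per year", 0.67 for "faster than 33% per
#' year".
#'
#' @param lambda a `lambda_summary` or a numeric vector of lambda draws.
#' @param threshold decline threshold on the lambda scale (default 1.0).
#' @return probability in [0, 1].
#' @export
decline_probability <- function(lambda, threshold = 1.0) {
  draws <- if (inherits(lambda, "lambda_summary")) lambda$draws else lambda
  if (length(draws) == 0) stop("no lambda draws", call. = FALSE)
  mean(draws < threshold)
}

#' Geometric-mean per-year change over the full study span
#'
#' Per-draw (B_last / B_first)^(1 / n_years_between), the constant annual
#' change that would produce the draw's total change.
#'
#' @param B matrix of B draws from [compute_B()].
#' @param retained optional logical mask over draws.
#' @return `lambda_summary`-like list with per-draw geometric means.
#' @export
geometric_mean_change <- function(B, retained = NULL) {
  if (is.null(retained)) retained <- rep(TRUE, nrow(B))
  yrs <- as.integer(colnames(B))
  span <- yrs[length(yrs)] - yrs[1]
  b1 <- B[retained, 1]
  b2 <- B[retained, ncol(B)]
  ok <- b1 > 0 & b2 > 0
  g <- (b2[ok] / b1[ok])^(1 / span)
  q <- stats::quantile(g, c(0.025, 0.975), names = FALSE)
  structure(list(t1 = yrs[1], t2 = yrs[length(yrs)], draws = g,
                 mean = mean(g), lower = q[1], upper = q[2],
                 percent_decline = (1 - mean(g)) * 100,
                 n_excluded = sum(!ok)),
            class = "lambda_summary")
}

#' Trend summary table
#'
#' The headline table of the analysis: for every successive year pair, the
#' posterior mean and 95% CRI of lambda, the probability of decline
#' (lambda < 1) and the probability of declining faster than 20% per year
#' (lambda < 0.8), plus a final row with the geometric-mean per-year change
#' over the whole span. With a `retained` mask the same table is computed
#' over the trajectory draws kept by a minimum-count update, which is how
#' the "after incorporation of sightings" column is produced — every lambda
#' in a trajectory comes from one joint posterior draw, so conditioning on
#' retention reweights all year pairs, including those before the update
#' years.
#'
#' @param draws a `geostat_draws` fit, or a precomputed B matrix.
#' @param retained optional logical mask over draws.
#' @return data frame of class `trend_table`: `period`, `lambda_mean`,
#'   `lambda_lower`, `lambda_upper`, `prob_declining_pct`,
#'   `prob_declining_gt20_pct`.
#' @export
trend_table <- function(draws, retained = NULL) {
  B <- if (inherits(draws, "geostat_draws")) compute_B(draws) else draws
  yrs <- as.integer(colnames(B))
  rows <- lapply(seq_len(length(yrs) - 1), function(k) {
    lam <- compute_lambda(B, yrs[k], yrs[k + 1], retained)
    data.frame(period = sprintf("%d-%d", yrs[k], yrs[k + 1]),
               lambda_mean = lam$mean,
               lambda_lower = lam$lower, lambda_upper = lam$upper,
               prob_declining_pct = 100 * decline_probability(lam, 1.0),
               prob_declining_gt20_pct = 100 * decline_probability(lam, 0.8),
               stringsAsFactors = FALSE)
  })
  g <- geometric_mean_change(B, retained)
  rows <- c(rows, list(data.frame(
    period = "geometric mean per-year",
    lambda_mean = g$mean, lambda_lower = g$lower, lambda_upper = g$upper,
    prob_declining_pct = 100 * decline_probability(g, 1.0),
    prob_declining_gt20_pct = 100 * decline_probability(g, 0.8),
    stringsAsFactors = FALSE)))
  out <- do.call(rbind, rows)
  class(out) <- c("trend_table", "data.frame")
  out
}

#' @export
print.trend_table <- function(x, ...) {
  y <- x
  y$lambda <- sprintf("%.2f (%.2f-%.2f)", y$lambda_mean,
                      y$lambda_lower, y$lambda_upper)
  y <- y[, c("period", "lambda", "prob_declining_pct",
             "prob_declining_gt20_pct")]
  names(y) <- c("period", "lambda (95% CRI)", "P(declining) %",
                "P(declining >20%/yr) %")
  y[[3]] <- sprintf("%.1f", y[[3]])
  y[[4]] <- sprintf("%.1f", y[[4]])
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Extract paired lambda draw streams for projection
#'
#' Returns the per-draw lambda values for a run of successive year pairs as
#' a matrix (draws x transitions), preserving the joint posterior coupling
#' between years within each draw; this is the input the abundance
#' projection multiplies trajectories by.
#'
#' @param draws a `geostat_draws` fit or B matrix.
#' @param from,to first and last year of the run (defaults: full span).
#' @return matrix with columns named "t1-t2" for each successive pair.
#' @export
lambda_streams <- function(draws, from = NULL, to = NULL) {
  B <- if (inherits(draws, "geostat_draws")) compute_B(draws) else draws
  yrs <- as.integer(colnames(B))
  if (is.null(from)) from <- yrs[1]
  if (is.null(to)) to <- yrs[length(yrs)]
  run <- yrs[yrs >= from & yrs <= to]
  if (length(run) < 2) stop("need at least two years in [from, to]",
                            call. = FALSE)
  out <- vapply(seq_len(length(run) - 1), function(k) {
    B[, as.character(run[k + 1])] / B[, as.character(run[k])]
  }, numeric(nrow(B)))
  colnames(out) <- sprintf("%d-%d", run[-length(run)], run[-1])
  out
}
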
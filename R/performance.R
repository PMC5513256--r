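#' Bias, variance and MSE of an abundance-based estimator over draws
#'
#' `bias = mean(estimates) - S_true`; `variance` is the population-convention
#' (1/n) variance of the estimates over draws; `mse = variance + bias^2`.
#'
#' @param estimates numeric vector of richness estimates, one per repeated
#'   sample (>= 2 draws).
#' @param S_true true richness of the assemblage.
#' @return object of class `performance_record`: list with `bias`,
#'   `variance`, `mse`, `n_draws`, `n_splits` (0), `fallback_count`.
#' @export
mse_abundance <- function(estimates, S_true) {
  if (length(estimates) < 2) stop("at least 2 draws are required")
  bias <- mean(estimates) - S_true
  v <- mean((estimates - mean(estimates))^2)
  structure(list(bias = bias, variance = v, mse = v + bias^2,
                 n_draws = length(estimates), n_splits = 0L,
                 fallback_count = 0L),
            class = "performance_record")
}

#' Two-component MSE of a split-based estimator
#'
#' The variance of a split-based estimate has two components: (1) the
#' variance of the per-draw aggregates over repeated draws, and (2) the
#' split-resampling contribution — the variance of the estimates across
#' the random splits within a draw, averaged over draws and scaled by the
#' number of splits the aggregate averages over (the variance of a mean of
#' `n_splits` split estimates is the per-split variance divided by
#' `n_splits`). With the default `n_splits = 1` the two components add
#' raw, the law-of-total-variance for a single random-split estimate.
#' Bias comes from the aggregates: `mse = variance + bias^2`.
#'
#' @param aggregates per-draw aggregated split estimates.
#' @param split_variances per-draw variances across splits (same length).
#' @param S_true true richness.
#' @param n_splits number of splits each aggregate averages over.
#' @return a `performance_record`.
#' @export
mse_split <- function(aggregates, split_variances, S_true, n_splits = 1) {
  if (length(aggregates) != length(split_variances))
    stop("`aggregates` and `split_variances` must have equal length")
  if (length(aggregates) < 2) stop("at least 2 draws are required")
  bias <- mean(aggregates) - S_true
  v <- mean((aggregates - mean(aggregates))^2) +
    mean(split_variances) / n_splits
  structure(list(bias = bias, variance = v, mse = v + bias^2,
                 n_draws = length(aggregates),
                 n_splits = as.integer(n_splits),
                 fallback_count = 0L),
            class = "performance_record")
}

#' @export
print.performance_record <- function(x, ...) {
  cat("Performance: bias = ", format(x$bias, digits = 5),
      ", variance = ", format(x$variance, digits = 5),
      ", MSE = ", format(x$mse, digits = 5),
      " (", x$n_draws, " draws)\n", sep = "")
  invisible(x)
}

#' Proportionate MSE difference between an incidence and an abundance route
#'
#' `(mse_incidence - mse_abundance) / min(mse_incidence, mse_abundance)`;
#' negative values favour the split incidence estimator. Undefined when
#' either MSE is zero (fully converged estimators); callers filter those.
#'
#' @param mse_incidence MSE of the split-based incidence estimator (> 0).
#' @param mse_abundance MSE of the single-sample abundance estimator (> 0).
#' @return signed proportionate difference (vectorized).
#' @export
proportionate_difference <- function(mse_incidence, mse_abundance) {
  if (any(mse_incidence <= 0) || any(mse_abundance <= 0))
    stop("proportionate difference is undefined when an MSE is zero")
  (mse_incidence - mse_abundance) / pmin(mse_incidence, mse_abundance)
}
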
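#' Randomly split an abundance sample into k equal sub-samples
#'
#' The `n` individuals (counts expanded to individuals) are randomly
#' permuted and dealt into `k` groups whose sizes differ by at most one
#' (the first `n %% k` groups receive the extra individual). Each group's
#' species set gives one presence/absence column of the returned incidence
#' set; this is a true partition, so reassembling the per-group counts
#' recovers the original sample exactly.
#'
#' @param sample an [abundance_sample()].
#' @param k number of sub-samples (>= 2).
#' @param seed optional integer for a reproducible split.
#' @return an [incidence_set()] over the `k` groups.
#' @export
#' @examples
#' s <- abundance_sample(c(a = 4, b = 3, c = 2, d = 1))
#' split_sample(s, k = 2, seed = 1)
split_sample <- function(sample, k = 2, seed = NULL) {
  stopifnot(inherits(sample, "abundance_sample"))
  if (!is.numeric(k) || k < 2 || k != round(k))
    stop("`k` must be an integer >= 2")
  n <- sample$n
  if (n < k) stop("sample size n = ", n, " is smaller than k = ", k)
  if (!is.null(seed)) set.seed(seed)
  individuals <- rep(seq_along(sample$counts), sample$counts)
  perm <- sample.int(n)
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  group <- rep(seq_len(k), sizes)
  cmat <- matrix(0L, nrow = sample$s_obs, ncol = k,
                 dimnames = list(names(sample$counts),
                                 paste0("split", seq_len(k))))
  for (g in seq_len(k)) {
    tab <- tabulate(individuals[perm[group == g]], nbins = sample$s_obs)
    cmat[, g] <- tab
  }
  out <- incidence_set(1L * (cmat > 0))
  attr(out, "group_counts") <- cmat  # per-group counts; rowSums == counts
  out
}

#' Split-based richness estimation aggregated over random re-partitions
#'
#' The core splitting method: partition a single abundance sample into `k`
#' equally sized sub-samples, apply an incidence-based estimator to the
#' resulting presence/absence data, and repeat over `n_splits` independent
#' random partitions. The aggregate (mean by default; the mean is slightly
#' more accurate than the median) is the richness estimate; the variance of
#' the per-split estimates is reported for use in the two-component MSE of
#' [mse_split()].
#'
#' @param sample an [abundance_sample()].
#' @param estimator_id one of the incidence estimators `"chao2_bc"`,
#'   `"jk1i"`, `"jk2i"`, `"ice"`. Abundance estimators are rejected with a
#'   pointer to the single-sample path.
#' @param k number of sub-samples per partition (default 2).
#' @param n_splits number of independent random partitions (default 300).
#' @param aggregate `"mean"` or `"median"`.
#' @param seed optional integer for reproducibility.
#' @return object of class `split_estimate`: list with `estimator_id`, `k`,
#'   `n_splits`, `per_split_estimates`, `aggregate` (the point estimate),
#'   `split_variance` (population-convention variance across splits; 0 when
#'   `n_splits = 1`) and `fallback_count`.
#' @export
#' @examples
#' a <- catch_probabilities(sad_params("lognormal", 20, 100, 0.8))
#' s <- draw_sample(a, 200, seed = 1)
#' split_estimate(s, "chao2_bc", n_splits = 25, seed = 2)
split_estimate <- function(sample,
                           estimator_id = c("chao2_bc", "jk1i", "jk2i", "ice"),
                           k = 2, n_splits = 300,
                           aggregate = c("mean", "median"), seed = NULL) {
  stopifnot(inherits(sample, "abundance_sample"))
  if (length(estimator_id) == 1 &&
      estimator_id %in% c("chao1_bc", "jk1a", "jk2a", "ace"))
    stop("`", estimator_id, "` is abundance-based: apply it directly to the ",
         "unsplit sample instead of using the splitting path")
  estimator_id <- match.arg(estimator_id)
  aggregate <- match.arg(aggregate)
  if (n_splits < 1) stop("`n_splits` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  fn <- switch(estimator_id,
               chao2_bc = chao2_bc,
               jk1i = function(x) jackknife_incidence(x, 1),
               jk2i = function(x) jackknife_incidence(x, 2),
               ice = ice)
  ests <- numeric(n_splits)
  fallbacks <- 0L
  for (i in seq_len(n_splits)) {
    inc <- split_sample(sample, k = k)
    r <- withCallingHandlers(
      fn(inc),
      warning = function(w) invokeRestart("muffleWarning"))
    if (isTRUE(r$fallback)) fallbacks <- fallbacks + 1L
    ests[i] <- r$estimate
  }
  agg <- if (aggregate == "mean") mean(ests) else stats::median(ests)
  structure(list(estimator_id = estimator_id, k = k, n_splits = n_splits,
                 per_split_estimates = ests,
                 aggregate = agg,
                 split_variance = if (n_splits > 1)
                   mean((ests - mean(ests))^2) else 0,
                 aggregate_type = aggregate,
                 fallback_count = fallbacks,
                 s_obs = sample$s_obs, n = sample$n),
            class = "split_estimate")
}

#' @export
print.split_estimate <- function(x, ...) {
  cat("Split estimate (", x$estimator_id, ", k = ", x$k, ", ",
      x$n_splits, " splits): ", format(x$aggregate, digits = 6),
      "  [", x$aggregate_type, "; split variance ",
      format(x$split_variance, digits = 4), "]\n", sep = "")
  invisible(x)
}
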
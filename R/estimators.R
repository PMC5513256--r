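#' Construct an incidence set from a presence/absence matrix
#'
#' @param mat species x sub-sample matrix of 0/1 (logical or numeric); row
#'   names identify species. Species absent from every sub-sample are
#'   dropped with a warning.
#' @return object of class `incidence_set`: list with `m` (number of
#'   sub-samples), `incidence` (named integer vector: number of sub-samples
#'   containing each species), `s_obs`, and `matrix` (the 0/1 matrix, kept
#'   for ICE's sample-number correction).
#' @export
incidence_set <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("at least m = 2 sub-samples are required")
  if (!all(mat %in% c(0, 1))) stop("incidence cells must be 0 or 1")
  storage.mode(mat) <- "integer"
  if (is.null(rownames(mat))) rownames(mat) <- as.character(seq_len(nrow(mat)))
  zero <- rowSums(mat) == 0
  if (any(zero)) {
    warning(sum(zero), " species observed in no sub-sample dropped")
    mat <- mat[!zero, , drop = FALSE]
  }
  if (nrow(mat) == 0) stop("incidence matrix contains no observed species")
  inc <- rowSums(mat)
  structure(list(m = ncol(mat),
                 incidence = stats::setNames(as.integer(inc), rownames(mat)),
                 s_obs = nrow(mat),
                 matrix = mat),
            class = "incidence_set")
}

#' @export
print.incidence_set <- function(x, ...) {
  q <- q_counts(x)
  cat("Incidence set: m = ", x$m, ", s_obs = ", x$s_obs,
      ", q1 = ", if ("1" %in% names(q)) q[["1"]] else 0L,
      ", q2 = ", if ("2" %in% names(q)) q[["2"]] else 0L, "\n", sep = "")
  invisible(x)
}

#' Incidence frequency counts
#'
#' `q_k`: number of species found in exactly `k` of the `m` sub-samples.
#'
#' @param inc an `incidence_set`.
#' @return named integer vector.
#' @export
q_counts <- function(inc) {
  stopifnot(inherits(inc, "incidence_set"))
  tab <- table(inc$incidence)
  q <- as.integer(tab)
  names(q) <- names(tab)
  q
}

# Assemble an estimate record. All estimators are truncated below at the
# observed richness (an estimate cannot fall short of what was seen); the
# untruncated value is kept in `raw`.
estimate_result <- function(estimator_id, estimate, s_obs, inputs,
                            fallback = FALSE) {
  structure(list(estimator_id = estimator_id,
                 estimate = max(estimate, s_obs),
                 raw = estimate,
                 s_obs = s_obs,
                 inputs = inputs,
                 fallback = fallback),
            class = "richness_estimate")
}

#' @export
print.richness_estimate <- function(x, ...) {
  cat(x$estimator_id, ": estimated richness = ",
      format(x$estimate, digits = 6), " (s_obs = ", x$s_obs, ")",
      if (x$fallback) " [fallback]", "\n", sep = "")
  invisible(x)
}

#' @export
as.numeric.richness_estimate <- function(x, ...) x$estimate

#' Bias-corrected Chao1 richness estimator (abundance data)
#'
#' `S_chao1 = s_obs + ((n-1)/n) * f1 (f1 - 1) / (2 (f2 + 1))`, defined also
#' when `f2 = 0` or `f1 <= 1`.
#'
#' @param sample an [abundance_sample()].
#' @return a `richness_estimate`.
#' @export
#' @examples
#' chao1_bc(abundance_sample(c(1, 1, 1, 2, 2, 5)))
chao1_bc <- function(sample) {
  stopifnot(inherits(sample, "abundance_sample"))
  f <- freq_of_freq(sample)
  f1 <- fk(f, 1); f2 <- fk(f, 2); n <- sample$n
  est <- sample$s_obs + (n - 1) / n * f1 * (f1 - 1) / (2 * (f2 + 1))
  estimate_result("chao1_bc", est, sample$s_obs,
                  list(n = n, f1 = f1, f2 = f2))
}

#' Bias-corrected Chao2 richness estimator (incidence data)
#'
#' `S_chao2 = s_obs + ((m-1)/m) * q1 (q1 - 1) / (2 (q2 + 1))`.
#'
#' @param inc an [incidence_set()] with `m >= 2` sub-samples.
#' @return a `richness_estimate`.
#' @export
chao2_bc <- function(inc) {
  stopifnot(inherits(inc, "incidence_set"))
  q <- q_counts(inc)
  q1 <- fk(q, 1); q2 <- fk(q, 2); m <- inc$m
  est <- inc$s_obs + (m - 1) / m * q1 * (q1 - 1) / (2 * (q2 + 1))
  estimate_result("chao2_bc", est, inc$s_obs,
                  list(m = m, q1 = q1, q2 = q2))
}

#' Abundance-based jackknife richness estimators
#'
#' Order 1: `s_obs + f1 (n-1)/n`. Order 2:
#' `s_obs + f1 (2n-3)/n - f2 (n-2)^2 / (n (n-1))`.
#'
#' @param sample an [abundance_sample()].
#' @param order 1 or 2.
#' @return a `richness_estimate` (id `jk1a` or `jk2a`).
#' @export
jackknife_abundance <- function(sample, order = 1) {
  stopifnot(inherits(sample, "abundance_sample"))
  if (!order %in% c(1, 2)) stop("`order` must be 1 or 2")
  n <- sample$n
  if (n < order + 1) stop("sample size too small for jackknife order ", order)
  f <- freq_of_freq(sample)
  f1 <- fk(f, 1); f2 <- fk(f, 2)
  est <- if (order == 1)
    sample$s_obs + f1 * (n - 1) / n
  else
    sample$s_obs + f1 * (2 * n - 3) / n - f2 * (n - 2)^2 / (n * (n - 1))
  estimate_result(paste0("jk", order, "a"), est, sample$s_obs,
                  list(n = n, f1 = f1, f2 = f2))
}

#' Incidence-based jackknife richness estimators
#'
#' Order 1: `s_obs + q1 (m-1)/m`. Order 2:
#' `s_obs + q1 (2m-3)/m - q2 (m-2)^2 / (m (m-1))`. For `m = 2` the
#' second-order correction term vanishes, so both orders coincide exactly.
#'
#' @param inc an [incidence_set()].
#' @param order 1 or 2.
#' @return a `richness_estimate` (id `jk1i` or `jk2i`).
#' @export
jackknife_incidence <- function(inc, order = 1) {
  stopifnot(inherits(inc, "incidence_set"))
  if (!order %in% c(1, 2)) stop("`order` must be 1 or 2")
  m <- inc$m
  q <- q_counts(inc)
  q1 <- fk(q, 1); q2 <- fk(q, 2)
  est <- if (order == 1)
    inc$s_obs + q1 * (m - 1) / m
  else
    inc$s_obs + q1 * (2 * m - 3) / m - q2 * (m - 2)^2 / (m * (m - 1))
  estimate_result(paste0("jk", order, "i"), est, inc$s_obs,
                  list(m = m, q1 = q1, q2 = q2))
}

#' Abundance-based coverage estimator (ACE)
#'
#' Species with counts at or below `rare_cutoff` form the rare class with
#' `S_rare` species and `N_rare` individuals; sample coverage is
#' `C = 1 - f1/N_rare`; the squared CV of the rare class is
#' `gamma^2 = max(S_rare/C * sum k(k-1) f_k / (N_rare (N_rare - 1)) - 1, 0)`
#' and `S_ace = S_abund + S_rare/C + (f1/C) gamma^2`. When every rare
#' individual is a singleton the coverage is zero and the estimator falls
#' back to [chao1_bc()] with a warning (flagged in the result).
#'
#' @param sample an [abundance_sample()].
#' @param rare_cutoff rare-class threshold (default 10).
#' @return a `richness_estimate`.
#' @export
ace <- function(sample, rare_cutoff = 10) {
  stopifnot(inherits(sample, "abundance_sample"))
  cnt <- sample$counts
  rare <- cnt[cnt <= rare_cutoff]
  s_abund <- sum(cnt > rare_cutoff)
  if (length(rare) == 0)
    return(estimate_result("ace", sample$s_obs, sample$s_obs,
                           list(n = sample$n, s_rare = 0L)))
  s_rare <- length(rare)
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  C <- 1 - f1 / n_rare
  if (C <= 0) {
    warning("ACE coverage is zero (all rare species are singletons); ",
            "falling back to chao1_bc")
    fb <- chao1_bc(sample)
    return(estimate_result("ace", fb$estimate, sample$s_obs,
                           fb$inputs, fallback = TRUE))
  }
  sk <- sum(rare * (rare - 1))
  g2 <- if (n_rare > 1)
    max(s_rare / C * sk / (n_rare * (n_rare - 1)) - 1, 0) else 0
  est <- s_abund + s_rare / C + f1 / C * g2
  estimate_result("ace", est, sample$s_obs,
                  list(n = sample$n, s_rare = s_rare, n_rare = n_rare,
                       f1 = f1, coverage = C, gamma2 = g2))
}

#' Incidence-based coverage estimator (ICE)
#'
#' Incidence analogue of [ace()]: species found in at most
#' `infrequent_cutoff` sub-samples form the infrequent class;
#' `C = 1 - q1/n_infreq` with `n_infreq` the total incidences of that class;
#' the squared CV carries the sample-number correction
#' `m_infreq/(m_infreq - 1)`, where `m_infreq` is the number of sub-samples
#' containing at least one infrequent species, and the denominator is
#' `n_infreq^2`. Falls back to [chao2_bc()] with a warning when the
#' coverage is zero or `m_infreq <= 1`.
#'
#' @param inc an [incidence_set()].
#' @param infrequent_cutoff infrequent-class threshold (default 10).
#' @return a `richness_estimate`.
#' @export
ice <- function(inc, infrequent_cutoff = 10) {
  stopifnot(inherits(inc, "incidence_set"))
  v <- inc$incidence
  infreq <- v[v <= infrequent_cutoff]
  s_freq <- sum(v > infrequent_cutoff)
  if (length(infreq) == 0)
    return(estimate_result("ice", inc$s_obs, inc$s_obs,
                           list(m = inc$m, s_infreq = 0L)))
  s_inf <- length(infreq)
  n_inf <- sum(infreq)
  q1 <- sum(infreq == 1)
  infreq_rows <- inc$matrix[v <= infrequent_cutoff, , drop = FALSE]
  m_inf <- sum(colSums(infreq_rows) > 0)
  C <- 1 - q1 / n_inf
  if (C <= 0 || m_inf <= 1) {
    warning("ICE undefined (coverage zero or m_infreq <= 1); ",
            "falling back to chao2_bc")
    fb <- chao2_bc(inc)
    return(estimate_result("ice", fb$estimate, inc$s_obs,
                           fb$inputs, fallback = TRUE))
  }
  sk <- sum(infreq * (infreq - 1))
  g2 <- max(s_inf / C * m_inf / (m_inf - 1) * sk / n_inf^2 - 1, 0)
  est <- s_freq + s_inf / C + q1 / C * g2
  estimate_result("ice", est, inc$s_obs,
                  list(m = inc$m, s_infreq = s_inf, n_infreq = n_inf,
                       q1 = q1, m_infreq = m_inf, coverage = C, gamma2 = g2))
}
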
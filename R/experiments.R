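#' Simulation scenario configuration
#'
#' Bundles the parameter-draw laws for a Monte Carlo sweep over simulated
#' assemblages: the SAD families, population-size range, richness rule,
#' sample-size rule, CV grid and replicate counts.
#'
#' @param sad_families character vector of SAD families.
#' @param n_assemblages assemblages simulated per CV grid point.
#' @param N_range range (low, high) for total abundance `N`, drawn
#'   uniformly.
#' @param S_rule function `N -> integer vector` of admissible richness
#'   values; `S` is drawn uniformly from it. The default scales richness
#'   with population size: `2 .. min(500, max(2, round(N/200)))`.
#' @param n_rule either `list(type = "absolute", range = c(lo, hi))` (sample
#'   size uniform on the range, redrawn together with `N` until `n < N`) or
#'   `list(type = "percent", range = c(lo, hi))` (sample size a uniform
#'   fraction of `N`).
#' @param cv_grid CV grid points.
#' @param n_draws repeated samples per assemblage.
#' @param n_splits random re-partitions per sample for the split estimators.
#' @param k_splits number of groups per partition (single integer).
#' @param seed integer seed governing the whole sweep.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(sad_families = "lognormal",
                            n_assemblages = 6000,
                            N_range = c(1e3, 1e5),
                            S_rule = default_S_rule,
                            n_rule = list(type = "absolute",
                                          range = c(300, 5000)),
                            cv_grid = seq(0.15, 1.15, by = 0.1),
                            n_draws = 1000,
                            n_splits = 300,
                            k_splits = 2,
                            seed = 1) {
  stopifnot(length(N_range) == 2, N_range[1] > 0, diff(N_range) >= 0,
            is.function(S_rule),
            n_rule$type %in% c("absolute", "percent"),
            length(n_rule$range) == 2, all(n_rule$range > 0),
            all(cv_grid >= 0), n_assemblages >= 1, n_draws >= 2,
            n_splits >= 1, k_splits >= 2)
  structure(list(sad_families = sad_families,
                 n_assemblages = n_assemblages, N_range = N_range,
                 S_rule = S_rule, n_rule = n_rule, cv_grid = cv_grid,
                 n_draws = n_draws, n_splits = n_splits,
                 k_splits = as.integer(k_splits), seed = as.integer(seed)),
            class = "scenario_config")
}

#' Default richness rule: S uniform on 2..min(500, max(2, round(N/200)))
#'
#' Richness scales with population size so large populations can be
#' species-rich (up to 500 species at N = 1e5) while small ones stay poor.
#'
#' @param N total abundance.
#' @return integer vector of admissible S values.
#' @export
default_S_rule <- function(N) seq(2L, max(2L, min(500L, as.integer(round(N / 200)))))

#' Main lognormal sweep configuration
#'
#' Lognormal assemblages with `N` uniform on `[1e3, 1e5]`, richness by the
#' default rule, sample size uniform on `[300, 5000]` with rejection until
#' `n < N`, CV grid 0.15, 0.25, ..., 1.15. Full-scale defaults are 6000
#' assemblages per CV, 1000 draws and 300 splits; pass smaller replicate
#' counts for desk-scale runs.
#'
#' @param n_assemblages,n_draws,n_splits,seed see [scenario_config()].
#' @param ... further arguments passed to [scenario_config()].
#' @return a `scenario_config`.
#' @export
main_scenario <- function(n_assemblages = 6000, n_draws = 1000,
                          n_splits = 300, seed = 1, ...) {
  scenario_config(sad_families = "lognormal",
                  n_assemblages = n_assemblages,
                  n_draws = n_draws, n_splits = n_splits, seed = seed, ...)
}

#' Small-population sweep configuration
#'
#' Sweeps the full 1--100% sampled fraction of small populations: `N`
#' uniform on `[100, 1000]`, `S` uniform on 2..20, `n` a uniform percentage
#' of `N`. Used for the convergence study and, with `N` in `[1e3, 1e4]` and
#' `S` in 2..10, for the non-lognormal SAD families.
#'
#' @param sad_families SAD families to sweep.
#' @param N_range,S_range ranges for `N` and `S`.
#' @param percent_range sampled fraction range (0--1 scale).
#' @param n_assemblages,n_draws,n_splits,cv_grid,seed see
#'   [scenario_config()].
#' @param ... further arguments passed to [scenario_config()].
#' @return a `scenario_config`.
#' @export
small_population_scenario <- function(sad_families = "lognormal",
                                      N_range = c(100, 1000),
                                      S_range = c(2, 20),
                                      percent_range = c(0.01, 1),
                                      n_assemblages = 10000,
                                      n_draws = 500, n_splits = 300,
                                      cv_grid = seq(0.15, 1.15, by = 0.1),
                                      seed = 1, ...) {
  lo <- S_range[1]; hi <- S_range[2]
  scenario_config(sad_families = sad_families,
                  n_assemblages = n_assemblages,
                  N_range = N_range,
                  S_rule = function(N) seq(as.integer(lo), as.integer(hi)),
                  n_rule = list(type = "percent", range = percent_range),
                  cv_grid = cv_grid,
                  n_draws = n_draws, n_splits = n_splits, seed = seed, ...)
}

#' Draw one assemblage parameter set from a scenario
#'
#' Draws `N` uniformly on the configured range, `S` uniformly from the
#' richness rule, and the sample size from the sample-size rule (absolute
#' rule: redraw `(N, n)` until `n < N`). Mean abundance is `N/S`. When the
#' SAD family cannot attain the requested CV at the drawn `S` (e.g. a
#' geometric series with 2 species cannot exceed CV 1), `(N, S)` is redrawn.
#'
#' @param config a [scenario_config()].
#' @param cv CV for this assemblage.
#' @param family SAD family (defaults to the first configured one).
#' @return list with `params` (a [sad_params()]) and `n` (sample size).
#' @export
draw_scenario_assemblage <- function(config, cv,
                                     family = config$sad_families[1]) {
  stopifnot(inherits(config, "scenario_config"))
  for (attempt in seq_len(200)) {
    N <- round(stats::runif(1, config$N_range[1], config$N_range[2]))
    if (config$n_rule$type == "absolute") {
      n <- round(stats::runif(1, config$n_rule$range[1],
                              config$n_rule$range[2]))
      if (n >= N) next  # rejection: sample must be smaller than population
    } else {
      pct <- stats::runif(1, config$n_rule$range[1], config$n_rule$range[2])
      n <- max(config$k_splits, round(pct * N))
    }
    Schoices <- config$S_rule(N)
    S <- Schoices[sample.int(length(Schoices), 1)]
    params <- tryCatch(sad_params(family, S, N / S, cv),
                       error = function(e) NULL)
    if (is.null(params)) next  # cv unattainable at this (family, S): redraw
    return(list(params = params, n = as.integer(n)))
  }
  stop("could not draw a feasible assemblage in 200 attempts (family = ",
       family, ", cv = ", cv, ")")
}

# Vectorized abundance estimators over a count matrix (species x draws).
# Mirrors chao1_bc/jackknife_abundance/ace exactly, including the floor at
# observed richness and the ACE -> Chao1 coverage fallback.
abundance_estimates_matrix <- function(C, n, rare_cutoff = 10) {
  s <- colSums(C > 0)
  f1 <- colSums(C == 1)
  f2 <- colSums(C == 2)
  chao1 <- s + (n - 1) / n * f1 * (f1 - 1) / (2 * (f2 + 1))
  jk1a <- s + f1 * (n - 1) / n
  jk2a <- pmax(s + f1 * (2 * n - 3) / n - f2 * (n - 2)^2 / (n * (n - 1)), s)
  rare <- C > 0 & C <= rare_cutoff
  s_rare <- colSums(rare)
  n_rare <- colSums(C * rare)
  s_abund <- s - s_rare
  sk <- colSums(C * (C - 1) * rare)
  cov <- 1 - f1 / n_rare
  g2 <- pmax(ifelse(n_rare > 1, s_rare / cov * sk / (n_rare * (n_rare - 1)),
                    0) - 1, 0)
  ace_v <- s_abund + s_rare / cov + f1 / cov * g2
  no_rare <- s_rare == 0
  fb <- !no_rare & cov <= 0
  ace_v[no_rare] <- s[no_rare]
  ace_v[fb] <- chao1[fb]
  list(est = list(chao1_bc = pmax(chao1, s), jk1a = pmax(jk1a, s),
                  jk2a = jk2a, ace = pmax(ace_v, s)),
       s_obs = s,
       fallbacks = c(chao1_bc = 0L, jk1a = 0L, jk2a = 0L, ace = sum(fb)))
}

# Vectorized incidence estimators from split q-statistics. Q has one row
# per (draw, split) and k columns (q_1..q_k); m = k sub-samples. Mirrors
# chao2_bc/jackknife_incidence/ice, including floors and the ICE -> Chao2
# fallback; in a partition every group holds at least one individual, so
# ICE's m_infreq equals k.
incidence_estimates_q <- function(Q, k) {
  s <- rowSums(Q)
  q1 <- Q[, 1]
  q2 <- Q[, 2]
  chao2 <- s + (k - 1) / k * q1 * (q1 - 1) / (2 * (q2 + 1))
  jk1i <- s + q1 * (k - 1) / k
  jk2i <- pmax(s + q1 * (2 * k - 3) / k - q2 * (k - 2)^2 / (k * (k - 1)), s)
  n_inf <- as.vector(Q %*% seq_len(k))
  sk <- as.vector(Q %*% (seq_len(k) * (seq_len(k) - 1)))
  cov <- 1 - q1 / n_inf
  g2 <- pmax(s / cov * k / (k - 1) * sk / n_inf^2 - 1, 0)
  ice_v <- s / cov + q1 / cov * g2
  fb <- cov <= 0
  ice_v[fb] <- chao2[fb]
  list(est = list(chao2_bc = pmax(chao2, s), jk1i = pmax(jk1i, s),
                  jk2i = jk2i, ice = pmax(ice_v, s)),
       fallbacks = c(chao2_bc = 0L, jk1i = 0L, jk2i = 0L, ice = sum(fb)))
}

#' Score every estimator on one assemblage by Monte Carlo MSE
#'
#' Draws `n_draws` samples of `n` individuals from the assemblage; applies
#' the four abundance estimators to each sample, and the four incidence
#' estimators to `n_splits` random `k`-way partitions of each sample
#' (aggregated by the mean); returns one performance row per estimator
#' with bias, variance (two-component for the split route) and MSE.
#'
#' @param assemblage a [catch_probabilities()] object.
#' @param n sample size per draw.
#' @param n_draws number of repeated samples.
#' @param n_splits number of random partitions per sample.
#' @param k number of groups per partition.
#' @return data.frame with columns `family,S,N,cv,n,estimator,bias,
#'   variance,mse,n_draws,n_splits,fallbacks,s_mean`.
#' @export
sweep_assemblage <- function(assemblage, n, n_draws, n_splits, k = 2) {
  stopifnot(inherits(assemblage, "assemblage"))
  p <- assemblage$params
  C <- stats::rmultinom(n_draws, n, assemblage$probs)
  ab <- abundance_estimates_matrix(C, n)
  Q <- split_qstats_cpp(C, as.integer(n_splits), as.integer(k))
  ic <- incidence_estimates_q(Q, k)
  S_true <- p$S
  rows <- list()
  for (id in names(ab$est)) {
    pr <- mse_abundance(ab$est[[id]], S_true)
    rows[[id]] <- data.frame(estimator = id, bias = pr$bias,
                             variance = pr$variance, mse = pr$mse,
                             n_splits = 0L, fallbacks = ab$fallbacks[[id]])
  }
  for (id in names(ic$est)) {
    e <- matrix(ic$est[[id]], nrow = n_splits)  # split index fastest
    aggs <- colMeans(e)
    svar <- colMeans(e^2) - aggs^2
    pr <- mse_split(aggs, svar, S_true, n_splits = n_splits)
    rows[[id]] <- data.frame(estimator = id, bias = pr$bias,
                             variance = pr$variance, mse = pr$mse,
                             n_splits = as.integer(n_splits),
                             fallbacks = ic$fallbacks[[id]])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  data.frame(family = p$family, S = S_true, N = p$N, cv = p$cv, n = n,
             out, n_draws = n_draws, s_mean = mean(ab$s_obs))
}

#' Run a full scenario sweep
#'
#' For every (family, CV grid point) cell, draws `n_assemblages` assemblage
#' parameter sets, scores all eight estimators on each via
#' [sweep_assemblage()], and returns the stacked performance table. Each
#' assemblage runs under its own derived RNG seed, so an interrupted sweep
#' resumed from a checkpoint reproduces the uninterrupted result.
#'
#' @param config a [scenario_config()].
#' @param checkpoint optional CSV path; finished assemblages are appended
#'   as they complete and skipped on re-run.
#' @param verbose print progress per cell.
#' @return data.frame of performance rows (one per assemblage x estimator)
#'   with an `assemblage_id` column.
#' @export
run_sweep <- function(config, checkpoint = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  done <- NULL
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    done <- utils::read.csv(checkpoint)
    if (nrow(done) == 0) done <- NULL
  }
  results <- if (is.null(done)) list() else list(done)
  done_ids <- if (is.null(done)) character() else unique(done$assemblage_id)
  cells <- expand.grid(family = config$sad_families, cv = config$cv_grid,
                       stringsAsFactors = FALSE)
  for (ci in seq_len(nrow(cells))) {
    family <- cells$family[ci]; cv <- cells$cv[ci]
    if (verbose)
      message(sprintf("sweep: family=%s cv=%.2f", family, cv))
    for (ai in seq_len(config$n_assemblages)) {
      id <- sprintf("%s_cv%.2f_a%04d", family, cv, ai)
      if (id %in% done_ids) next
      seed_i <- (config$seed + 104729 * ci + ai) %% 2147483647L
      set.seed(seed_i)
      drawn <- draw_scenario_assemblage(config, cv, family)
      asm <- catch_probabilities(drawn$params)
      row <- sweep_assemblage(asm, drawn$n, config$n_draws,
                              config$n_splits, config$k_splits)
      row <- data.frame(assemblage_id = id, row)
      results[[length(results) + 1L]] <- row
      if (!is.null(checkpoint))
        utils::write.table(row, checkpoint, sep = ",", append = file.exists(checkpoint),
                           col.names = !file.exists(checkpoint),
                           row.names = FALSE, quote = FALSE)
    }
  }
  out <- do.call(rbind, results)
  rownames(out) <- NULL
  out
}

#' Draw (N, n) design pairs for the main sweep parameter law
#'
#' Vectorized draw of population sizes `N` (uniform) and sample sizes `n`
#' (uniform), rejecting and redrawing pairs until `n < N`. The mean of
#' `n/N` under this law is the design's implied mean sampled fraction.
#'
#' @param n_pairs number of pairs.
#' @param N_range,n_range uniform draw ranges.
#' @return data.frame with columns `N` and `n`.
#' @export
draw_design_pairs <- function(n_pairs, N_range = c(1e3, 1e5),
                              n_range = c(300, 5000)) {
  N <- numeric(0); n <- numeric(0)
  while (length(N) < n_pairs) {
    todo <- n_pairs - length(N)
    Ni <- round(stats::runif(todo, N_range[1], N_range[2]))
    ni <- round(stats::runif(todo, n_range[1], n_range[2]))
    ok <- ni < Ni
    N <- c(N, Ni[ok]); n <- c(n, ni[ok])
  }
  data.frame(N = N, n = n)
}

#' Pivot a sweep table to one row per assemblage with per-estimator MSEs
#'
#' @param records output of [run_sweep()].
#' @return data.frame with one row per assemblage: design columns plus
#'   `mse_<estimator>` (and `bias_`/`variance_`) columns and
#'   `n_over_s = n / s_mean`.
#' @export
pair_mse_table <- function(records) {
  keys <- unique(records[, c("assemblage_id", "family", "S", "N", "cv",
                             "n", "s_mean")])
  for (id in unique(records$estimator)) {
    sub <- records[records$estimator == id, c("assemblage_id", "mse")]
    names(sub)[2] <- paste0("mse_", id)
    keys <- merge(keys, sub, by = "assemblage_id", sort = FALSE)
  }
  keys$n_over_s <- keys$n / keys$s_mean
  keys
}
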
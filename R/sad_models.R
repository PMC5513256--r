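#' Species-abundance distribution parameters
#'
#' Defines a theoretical species assemblage by its SAD family, true richness
#' `S`, mean abundance per species and coefficient of variation (CV) of
#' per-species abundance. Family-specific parameters are derived internally:
#' lognormal `(mu, sigma)` from the moment identities
#' `sigma^2 = log(1 + cv^2)`, `mu = log(mean_abundance) - sigma^2/2`;
#' geometric and log-series decay parameter `x` by root-finding so that the
#' ranked abundance vector of length `S` has the requested CV; negative
#' binomial `(r, p)` from `r = mean^2/(var - mean)`, `p = mean/var` with
#' `var = (cv * mean)^2`.
#'
#' @param family one of `"lognormal"`, `"log_series"`, `"geometric"`,
#'   `"negative_binomial"`.
#' @param S true species richness (positive integer).
#' @param mean_abundance mean number of individuals per species (> 0).
#' @param cv coefficient of variation of per-species abundance (> 0; a value
#'   of 0 is accepted and means a perfectly even community).
#' @return an object of class `sad_params`: a list with `family`, `S`,
#'   `mean_abundance`, `cv`, `N` (total abundance `S * mean_abundance`) and
#'   `derived` (the family-specific parameter record).
#' @seealso [catch_probabilities()] to turn parameters into ranked catch
#'   probabilities.
#' @export
#' @examples
#' sad_params("lognormal", S = 60, mean_abundance = 1000, cv = 0.95)
sad_params <- function(family = c("lognormal", "log_series", "geometric",
                                  "negative_binomial"),
                       S, mean_abundance, cv) {
  family <- match.arg(family)
  if (!is.numeric(S) || length(S) != 1L || S < 1 || S != round(S))
    stop("`S` must be a positive integer")
  if (!is.numeric(mean_abundance) || mean_abundance <= 0)
    stop("`mean_abundance` must be positive")
  if (!is.numeric(cv) || cv < 0)
    stop("`cv` must be non-negative")
  S <- as.integer(S)
  derived <- switch(family,
    lognormal = {
      d <- lognormal_derived(mean_abundance, max(cv, 0))
      list(mu = d[["mu"]], sigma = d[["sigma"]])
    },
    log_series = ,
    geometric = ,
    negative_binomial = series_params_from_cv(family, S, mean_abundance, cv)
  )
  structure(
    list(family = family, S = S, mean_abundance = mean_abundance,
         cv = cv, N = S * mean_abundance, derived = derived),
    class = "sad_params")
}

#' @export
print.sad_params <- function(x, ...) {
  cat("SAD parameters (", x$family, ")\n", sep = "")
  cat("  S = ", x$S, ", mean abundance = ", format(x$mean_abundance),
      ", CV = ", format(x$cv), ", N = ", format(x$N), "\n", sep = "")
  cat("  derived: ",
      paste(names(x$derived), format(unlist(x$derived), digits = 6),
            sep = " = ", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Lognormal moment parameters from mean and CV
#'
#' Moment identities of the lognormal: `sigma = sqrt(log(1 + cv^2))` and
#' `mu = log(mean_abundance) - sigma^2/2`, so that
#' `exp(mu + sigma^2/2) = mean_abundance`.
#'
#' @param mean_abundance mean abundance per species (> 0).
#' @param cv coefficient of variation (>= 0).
#' @return named numeric vector `c(mu, sigma)`.
#' @export
lognormal_derived <- function(mean_abundance, cv) {
  if (!is.numeric(mean_abundance) || mean_abundance <= 0)
    stop("`mean_abundance` must be positive")
  if (!is.numeric(cv) || cv < 0)
    stop("`cv` must be non-negative")
  sigma <- sqrt(log(1 + cv^2))
  c(mu = log(mean_abundance) - sigma^2 / 2, sigma = sigma)
}

# Midpoint rank quantiles (i - 0.5)/S, most common species first.
# Using midpoints keeps the quantile strictly inside (0, 1), so the normal
# quantile never diverges, and preserves the common/rare symmetry.
rank_quantiles <- function(S) (seq_len(S) - 0.5) / S

#' Ranked lognormal abundance weights
#'
#' Unnormalized per-species abundance weights for a lognormal SAD, obtained
#' by inverting the lognormal species-accumulation CDF at the midpoint rank
#' quantiles `p_i = (i - 0.5)/S`:
#' `w_i = exp(-sigma * sqrt(2) * erfinv(2 p_i - 1)) = exp(-sigma * qnorm(p_i))`.
#' Rank 1 is the most common species; with midpoint quantiles
#' `w_i * w_(S+1-i) = 1` (the error-function inverse is odd).
#'
#' @param S number of species (>= 1).
#' @param sigma lognormal standard deviation on the log scale (>= 0).
#' @return numeric vector of length `S`, non-increasing.
#' @export
lognormal_ranked_weights <- function(S, sigma) {
  if (!is.numeric(S) || length(S) != 1L || S < 1 || S != round(S))
    stop("`S` must be a positive integer")
  if (!is.numeric(sigma) || sigma < 0)
    stop("`sigma` must be non-negative")
  p <- rank_quantiles(S)
  stopifnot(all(p > 0 & p < 1))  # midpoint convention guarantees this
  exp(-sigma * stats::qnorm(p))
}

# Population-convention coefficient of variation of a vector.
cv_pop <- function(w) {
  m <- mean(w)
  sqrt(mean((w - m)^2)) / m
}

# Piecewise-linear quantile of a discrete distribution with pmf over
# integer support `support` (ascending). Interpolates between successive
# (CDF, value) anchors so ranked weights vary continuously with the family
# parameter; abundances are kept real-valued by design.
interp_quantile <- function(u, support, pmf) {
  cdf <- cumsum(pmf) / sum(pmf)
  x <- c(0, cdf)
  y <- c(support[1], support)  # flat first segment at the support minimum
  stats::approx(x, y, xout = pmin(u, 1), ties = "ordered", rule = 2)$y
}

# logarithmic-distribution pmf over 1..nmax, truncated adaptively
logseries_pmf <- function(x, upper_q) {
  nmax <- 64L
  repeat {
    n <- seq_len(nmax)
    pmf <- x^n / n
    cdf <- cumsum(pmf) / (-log1p(-x))
    if (cdf[nmax] >= upper_q || nmax >= 2^22) return(list(n = n, pmf = pmf))
    nmax <- nmax * 4L
  }
}

# Ranked weights (most common first) for the three discrete/series families.
series_ranked_weights <- function(family, S, x = NULL, r = NULL, p = NULL) {
  q <- 1 - rank_quantiles(S)  # upper-tail quantile for rank i
  switch(family,
    geometric = x^(seq_len(S) - 1),
    log_series = {
      pm <- logseries_pmf(x, max(q))
      rev(sort(interp_quantile(q, pm$n, pm$pmf)))
    },
    negative_binomial = {
      # zero-truncated NB so every species has positive expected abundance
      nmax <- stats::qnbinom(1 - 1e-12, size = r, prob = p) + 1
      n <- seq_len(nmax)
      pmf <- stats::dnbinom(n, size = r, prob = p)
      rev(sort(interp_quantile(q, n, pmf))) },
    stop("unknown family: ", family))
}

#' Series-family parameters matching a target CV
#'
#' Finds the family parameter(s) so that the ranked abundance vector of
#' length `S` has (population-convention) coefficient of variation `cv`.
#' For geometric and log-series this is a root-finding problem in the decay
#' parameter `x`, solved to |cv(w) - cv| < 1e-6; for the negative binomial
#' the closed-form moment mapping `r = mean^2/(var - mean)`, `p = mean/var`
#' is used (requires `var > mean`, i.e. `cv^2 * mean_abundance > 1`).
#'
#' @param family `"log_series"`, `"geometric"` or `"negative_binomial"`.
#' @param S number of species.
#' @param mean_abundance mean abundance per species.
#' @param cv target coefficient of variation of the ranked abundances.
#' @return a list with the family parameters (`x` for the series families,
#'   `r` and `p` for the negative binomial).
# solved decay parameters depend only on (family, S, cv); cache them so
# sweeps that revisit the same cell skip the root-finding
.series_cache <- new.env(parent = emptyenv())

#' @export
series_params_from_cv <- function(family, S, mean_abundance, cv) {
  family <- match.arg(family,
                      c("log_series", "geometric", "negative_binomial"))
  if (cv < 0) stop("`cv` must be non-negative")
  if (family == "negative_binomial") {
    v <- (cv * mean_abundance)^2
    if (v <= mean_abundance)
      stop("negative binomial requires variance > mean: need cv > ",
           format(1 / sqrt(mean_abundance)),
           " at mean abundance ", format(mean_abundance))
    return(list(r = mean_abundance^2 / (v - mean_abundance),
                p = mean_abundance / v))
  }
  key <- sprintf("%s_%d_%.12g", family, S, cv)
  out <- .series_cache[[key]]
  if (is.null(out)) {
    out <- tryCatch(series_solve_x(family, S, cv), error = function(e) e)
    assign(key, out, envir = .series_cache)
  }
  if (inherits(out, "error")) stop(out)
  out
}

# root-finding for the decay parameter of the geometric / log-series rank
# abundance construction
series_solve_x <- function(family, S, cv) {
  if (S == 1) {
    if (cv > 0)
      stop("a single-species assemblage has cv = 0; cv = ", cv,
           " is not attainable (attainable range: {0})")
    return(list(x = if (family == "geometric") 1 - 1e-9 else 1e-9))
  }
  if (cv == 0)  # even-community limit: x -> 1 (geometric), x -> 0 (log series)
    return(list(x = if (family == "geometric") 1 - 1e-9 else 1e-9))
  fcv <- function(x) cv_pop(series_ranked_weights(family, S, x = x))
  lo <- 1e-9
  hi <- if (family == "log_series") 1 - 1e-6 else 1 - 1e-9
  cv_lo <- fcv(lo); cv_hi <- fcv(hi)
  cv_min <- min(cv_lo, cv_hi); cv_max <- max(cv_lo, cv_hi)
  if (cv < cv_min - 1e-9 || cv > cv_max + 1e-9)
    stop(sprintf(
      "cv = %g not attainable for %s with S = %d; attainable range is [%g, %g]",
      cv, family, S, cv_min, cv_max))
  if (cv <= cv_min)  # at or below the boundary: take the limiting parameter
    return(list(x = if (cv_lo < cv_hi) lo else hi))
  if (cv >= cv_max)
    return(list(x = if (cv_lo > cv_hi) lo else hi))
  root <- stats::uniroot(function(x) fcv(x) - cv, c(lo, hi), tol = 1e-12)
  x <- root$root
  if (abs(fcv(x) - cv) > 1e-6)
    stop("root-finding failed to match cv within 1e-6 for ", family)
  list(x = x)
}

#' Ranked catch probabilities of an assemblage
#'
#' Converts SAD parameters to the ranked per-species catch-probability
#' vector: the family's abundance-by-rank weights, evaluated at the midpoint
#' rank quantiles, normalized to sum to one. Catch probability is
#' proportional to abundance (individuals are equally catchable regardless
#' of species identity), so `probs` drives inverse-CDF sampling of
#' individuals and `abundances = probs * N` are the expected per-species
#' abundances.
#'
#' @param params a [sad_params()] object.
#' @return an object of class `assemblage`: list with `params`, `probs`
#'   (non-increasing, sums to 1), `cumprobs`, `abundances`.
#' @export
#' @examples
#' a <- catch_probabilities(sad_params("lognormal", 60, 1000, 0.95))
#' head(a$probs)
catch_probabilities <- function(params) {
  if (!inherits(params, "sad_params"))
    stop("`params` must be a `sad_params` object")
  w <- switch(params$family,
    lognormal = lognormal_ranked_weights(params$S, params$derived$sigma),
    geometric = series_ranked_weights("geometric", params$S,
                                      x = params$derived$x),
    log_series = series_ranked_weights("log_series", params$S,
                                       x = params$derived$x),
    negative_binomial = series_ranked_weights(
      "negative_binomial", params$S,
      r = params$derived$r, p = params$derived$p))
  if (any(!is.finite(w)) || any(w < 0))
    stop("degenerate ranked weights for the given parameters")
  probs <- w / sum(w)
  structure(
    list(params = params,
         probs = probs,
         cumprobs = cumsum(probs),
         abundances = probs * params$N),
    class = "assemblage")
}

#' @export
print.assemblage <- function(x, ...) {
  cat("Assemblage: ", x$params$family, " SAD, S = ", x$params$S,
      ", N = ", format(x$params$N), ", CV = ", format(x$params$cv),
      "\n", sep = "")
  cat("  top catch probabilities:",
      paste(format(utils::head(x$probs, 5), digits = 4), collapse = ", "),
      if (x$params$S > 5) "...", "\n")
  invisible(x)
}

#' Write an assemblage to TSV
#'
#' Columns `rank`, `probability`, `expected_abundance`, with header.
#'
#' @param assemblage an `assemblage` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_assemblage <- function(assemblage, path) {
  stopifnot(inherits(assemblage, "assemblage"))
  df <- data.frame(rank = seq_along(assemblage$probs),
                   probability = assemblage$probs,
                   expected_abundance = assemblage$abundances)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an assemblage TSV written by [write_assemblage()]
#'
#' Reconstructs the probability vector (renormalized against rounding) and
#' expected abundances; the `params` slot records only the total abundance.
#'
#' @param path input file path.
#' @return an `assemblage`-like object (class `assemblage`) with `params`
#'   set to `NULL` family information.
#' @export
read_assemblage <- function(path) {
  df <- utils::read.delim(path, fileEncoding = "UTF-8")
  need <- c("rank", "probability", "expected_abundance")
  if (!all(need %in% names(df)))
    stop("assemblage file must have columns: ", paste(need, collapse = ", "))
  df <- df[order(df$rank), ]
  probs <- df$probability / sum(df$probability)
  structure(
    list(params = list(family = NA_character_, S = nrow(df),
                       N = sum(df$expected_abundance)),
         probs = probs,
         cumprobs = cumsum(probs),
         abundances = df$expected_abundance),
    class = "assemblage")
}
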
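#' Construct an abundance sample from species counts
#'
#' @param counts named (or unnamed) vector of non-negative integer counts;
#'   zero counts are dropped. Names default to the integer rank.
#' @return an object of class `abundance_sample`: list with `counts` (named
#'   integer vector of positive counts), `n` (total individuals) and `s_obs`
#'   (number of observed species).
#' @export
abundance_sample <- function(counts) {
  if (length(counts) == 0 || !is.numeric(counts))
    stop("`counts` must be a non-empty numeric vector")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("`counts` must be non-negative integers")
  if (is.null(names(counts))) names(counts) <- as.character(seq_along(counts))
  counts <- counts[counts > 0]
  if (length(counts) == 0) stop("sample contains no individuals")
  storage.mode(counts) <- "integer"
  structure(list(counts = counts,
                 n = sum(counts),
                 s_obs = length(counts)),
            class = "abundance_sample")
}

#' @export
print.abundance_sample <- function(x, ...) {
  f <- freq_of_freq(x)
  cat("Abundance sample: n = ", x$n, ", s_obs = ", x$s_obs,
      ", f1 = ", if ("1" %in% names(f)) f[["1"]] else 0L,
      ", f2 = ", if ("2" %in% names(f)) f[["2"]] else 0L, "\n", sep = "")
  invisible(x)
}

#' Draw a sample of individuals from an assemblage
#'
#' Inverse-CDF sampling with replacement: `n` uniform(0,1) numbers are
#' mapped to species ranks through the assemblage's cumulative catch
#' probabilities (half-open intervals `[cum[i-1], cum[i])`), and the drawn
#' ranks tabulated.
#'
#' @param assemblage an [catch_probabilities()] object.
#' @param n sample size (number of individuals, >= 1).
#' @param seed optional integer; when given, the draw is reproducible.
#' @return an [abundance_sample()] whose names are the species ranks.
#' @export
#' @examples
#' a <- catch_probabilities(sad_params("lognormal", 20, 100, 0.5))
#' draw_sample(a, 50, seed = 1)
draw_sample <- function(assemblage, n, seed = NULL) {
  stopifnot(inherits(assemblage, "assemblage"))
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("`n` must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(n)
  ranks <- findInterval(u, assemblage$cumprobs,
                        left.open = FALSE, rightmost.closed = TRUE) + 1L
  cnt <- tabulate(ranks, nbins = length(assemblage$probs))
  names(cnt) <- as.character(seq_along(cnt))
  abundance_sample(cnt)
}

#' Frequency of frequencies
#'
#' `f_k`: number of species observed exactly `k` times. `sum(f_k) = s_obs`
#' and `sum(k * f_k) = n`.
#'
#' @param sample an `abundance_sample`.
#' @return named integer vector, names are the counts `k` present.
#' @export
freq_of_freq <- function(sample) {
  stopifnot(inherits(sample, "abundance_sample"))
  tab <- table(sample$counts)
  f <- as.integer(tab)
  names(f) <- names(tab)
  f
}

# f_k lookup helper (0 when k absent)
fk <- function(f, k) {
  i <- match(as.character(k), names(f))
  ifelse(is.na(i), 0L, f[i])
}
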
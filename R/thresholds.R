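#' Critical sample-size-to-richness ratio from proportionate differences
#'
#' Locates the ratio `n/s` beyond which the split incidence estimator is
#' more likely than not (mid-criterion, fraction > 0.5) or almost surely
#' (edge-criterion, fraction >= 0.95) to beat its abundance counterpart.
#' Assemblages are binned by `n/s` into equal-count (quantile) bins; per
#' bin, the fraction of negative proportionate MSE differences is computed;
#' the criterion point is the midpoint of the lowest bin from which the
#' fraction satisfies the criterion in that bin and every larger bin.
#'
#' @param n_over_s per-assemblage sample-size-to-observed-richness ratios.
#' @param pd per-assemblage proportionate MSE differences
#'   ([proportionate_difference()]; negative favours the split route).
#' @param criterion `"mid"` (> 0.5) or `"edge"` (>= 0.95).
#' @param bins number of quantile bins (default 10).
#' @return list with `value` (the critical ratio; `NA` when the criterion
#'   is never met), `crossed` (logical), `criterion`, and the per-bin table
#'   `bins` (midpoint, fraction negative, count).
#' @export
critical_ratio <- function(n_over_s, pd, criterion = c("mid", "edge"),
                           bins = 10) {
  criterion <- match.arg(criterion)
  keep <- is.finite(n_over_s) & is.finite(pd)
  n_over_s <- n_over_s[keep]; pd <- pd[keep]
  if (length(pd) < 20)
    stop("at least 20 assemblages are required to locate a critical ratio")
  br <- unique(stats::quantile(n_over_s, probs = seq(0, 1, length.out = bins + 1)))
  if (length(br) < 3) stop("n/s values too degenerate to bin")
  bin <- cut(n_over_s, br, include.lowest = TRUE)
  mid <- (br[-length(br)] + br[-1]) / 2
  frac <- tapply(pd < 0, bin, mean)
  cnt <- tapply(pd, bin, length)
  thr <- if (criterion == "mid") 0.5 else 0.95
  ok <- if (criterion == "mid") frac > thr else frac >= thr
  ok[is.na(ok)] <- FALSE
  # lowest bin from which the criterion holds for all larger bins
  holds_up <- rev(cumprod(rev(ok))) > 0
  tab <- data.frame(midpoint = mid, fraction_negative = as.vector(frac),
                    count = as.vector(cnt))
  if (!any(holds_up))
    return(list(value = NA_real_, crossed = FALSE, criterion = criterion,
                bins = tab))
  list(value = mid[[which(holds_up)[1]]], crossed = TRUE,
       criterion = criterion, bins = tab)
}

#' Fit the power-law threshold curve (n/s)_C = a * CV^b
#'
#' Nonlinear least squares, initialized from a log-log linear regression.
#'
#' @param points data.frame (or list) with columns/elements `cv` and
#'   `critical_ratio` (>= 3 positive points).
#' @return list with `a`, `b`, `residual_norm` and the `fit` object.
#' @export
#' @examples
#' cv <- seq(0.25, 1.15, by = 0.1)
#' fit_power_law(data.frame(cv = cv, critical_ratio = 80.10 * cv^2.05))
fit_power_law <- function(points) {
  cv <- points$cv; r <- points$critical_ratio
  keep <- is.finite(cv) & is.finite(r)
  cv <- cv[keep]; r <- r[keep]
  if (length(cv) < 3) stop("at least 3 points are required")
  if (any(cv <= 0) || any(r <= 0)) stop("points must be positive")
  init <- stats::lm(log(r) ~ log(cv))
  start <- list(a = exp(stats::coef(init)[[1]]), b = stats::coef(init)[[2]])
  sse0 <- sum((r - start$a * cv^start$b)^2)
  if (sse0 <= 1e-18 * sum(r^2))  # log-log start already fits exactly
    return(list(a = start$a, b = start$b, residual_norm = sqrt(sse0),
                fit = NULL))
  fit <- tryCatch(
    minpack.lm::nlsLM(r ~ a * cv^b, data = data.frame(cv = cv, r = r),
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e)
      stop("power-law fit failed to converge (start a = ",
           format(start$a), ", b = ", format(start$b), "): ",
           conditionMessage(e)))
  cf <- stats::coef(fit)
  list(a = cf[["a"]], b = cf[["b"]],
       residual_norm = sqrt(sum(stats::resid(fit)^2)), fit = fit)
}

#' Cubic fit of the critical ratio against population abundance
#'
#' Ordinary least-squares polynomial of degree 3 in `N`.
#'
#' @param points data.frame with columns `N` and `critical_ratio`
#'   (>= 4 points).
#' @return named numeric vector of coefficients (intercept first).
#' @export
fit_poly_N <- function(points) {
  N <- points$N; r <- points$critical_ratio
  keep <- is.finite(N) & is.finite(r)
  N <- N[keep]; r <- r[keep]
  if (length(N) < 4) stop("at least 4 points are required")
  fit <- stats::lm(r ~ poly(N, 3, raw = TRUE))
  if (any(is.na(stats::coef(fit)))) stop("rank-deficient cubic fit")
  cf <- stats::coef(fit)
  names(cf) <- c("c0", "c1", "c2", "c3")
  cf
}

#' Fit a threshold model for one estimator pair
#'
#' Extracts the per-CV critical ratios ([critical_ratio()]) from a sweep
#' table and fits the power law ([fit_power_law()]). The pairs follow the
#' decision rule: `"chao2_vs_chao1"` compares split Chao2 against
#' single-sample Chao1, `"jk_i_vs_jk1a"` compares the split incidence
#' Jackknife against the abundance first-order Jackknife.
#'
#' @param records sweep table from [run_sweep()] (lognormal main sweep).
#' @param pair `"chao2_vs_chao1"` or `"jk_i_vs_jk1a"`.
#' @param criterion `"mid"` or `"edge"`.
#' @param N_range restrict to assemblages with `N` inside this range.
#' @param bins quantile bins per CV cell.
#' @return object of class `threshold_model`: list with `pair`,
#'   `criterion`, `N_range`, `a`, `b`, `fit_points`, and (when >= 4 CV
#'   points) `poly_N = NULL` placeholder for [fit_poly_N()] output.
#' @export
fit_threshold_model <- function(records,
                                pair = c("chao2_vs_chao1", "jk_i_vs_jk1a"),
                                criterion = c("mid", "edge"),
                                N_range = c(1e3, 1e5), bins = 10) {
  pair <- match.arg(pair)
  criterion <- match.arg(criterion)
  wide <- pair_mse_table(records)
  wide <- wide[wide$N >= N_range[1] & wide$N <= N_range[2], ]
  inc <- if (pair == "chao2_vs_chao1") "mse_chao2_bc" else "mse_jk1i"
  abn <- if (pair == "chao2_vs_chao1") "mse_chao1_bc" else "mse_jk1a"
  pts <- lapply(sort(unique(wide$cv)), function(cvv) {
    sub <- wide[wide$cv == cvv & wide[[inc]] > 0 & wide[[abn]] > 0, ]
    if (nrow(sub) < 20) return(NULL)
    cr <- critical_ratio(sub$n_over_s,
                         proportionate_difference(sub[[inc]], sub[[abn]]),
                         criterion = criterion, bins = bins)
    if (!cr$crossed) return(NULL)
    data.frame(cv = cvv, critical_ratio = cr$value)
  })
  fit_points <- do.call(rbind, pts)
  if (is.null(fit_points) || nrow(fit_points) < 3)
    stop("fewer than 3 CV cells produced a crossing; cannot fit the curve")
  pw <- fit_power_law(fit_points)
  structure(list(pair = pair, criterion = criterion, N_range = N_range,
                 a = pw$a, b = pw$b, fit_points = fit_points,
                 residual_norm = pw$residual_norm, poly_N = NULL),
            class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat("Threshold model [", x$pair, ", ", x$criterion, "-criterion, N in (",
      format(x$N_range[1]), ", ", format(x$N_range[2]), ")]\n", sep = "")
  cat("  (n/s)_C = ", format(x$a, digits = 5), " * CV^",
      format(x$b, digits = 4), "  (", nrow(x$fit_points),
      " CV points)\n", sep = "")
  invisible(x)
}

#' Predicted critical ratio at a CV
#'
#' @param model a `threshold_model`.
#' @param cv coefficient of variation.
#' @return predicted `(n/s)_C`.
#' @export
predict_critical_ratio <- function(model, cv) {
  stopifnot(inherits(model, "threshold_model"))
  model$a * cv^model$b
}

#' Locate the CV at which the best split estimator switches
#'
#' Above the critical `n/s` ratio, the best-performing split-based
#' estimator switches from Chao2 (even communities) to the incidence
#' Jackknife (uneven communities) as the CV grows. This restricts each CV
#' cell of a lognormal sweep to assemblages whose `n/s` exceeds both fitted
#' mid-criterion curves, compares the mean MSE of split Chao2 and split
#' Jackknife1i per cell, and reports the boundary CV as the midpoint of the
#' grid interval that best separates Chao2 wins (below) from Jackknife wins
#' (above).
#'
#' @param records sweep table from [run_sweep()].
#' @param model_chao,model_jk mid-criterion `threshold_model`s for the two
#'   estimator pairs (see [fit_threshold_model()]).
#' @return list with `boundary` (the crossover CV; `NA` if one estimator
#'   wins everywhere) and `winners` (per-CV table of mean MSEs, the winner
#'   and the number of assemblages used).
#' @export
split_estimator_crossover <- function(records, model_chao, model_jk) {
  wide <- pair_mse_table(records)
  cvs <- sort(unique(wide$cv))
  rows <- lapply(cvs, function(cvv) {
    thr <- max(predict_critical_ratio(model_chao, cvv),
               predict_critical_ratio(model_jk, cvv))
    sub <- wide[wide$cv == cvv & wide$n_over_s > thr, ]
    data.frame(cv = cvv, threshold = thr, n_used = nrow(sub),
               mse_chao2 = mean(sub$mse_chao2_bc),
               mse_jk = mean(sub$mse_jk1i))
  })
  winners <- do.call(rbind, rows)
  winners$winner <- ifelse(winners$mse_chao2 <= winners$mse_jk,
                           "chao2", "jackknife")
  ok <- winners$n_used >= 5 & is.finite(winners$mse_chao2) &
    is.finite(winners$mse_jk)
  w <- winners[ok, ]
  if (nrow(w) < 2)
    return(list(boundary = NA_real_, winners = winners))
  # split point maximizing (chao2 wins below) + (jackknife wins above)
  chao_below <- cumsum(w$winner == "chao2")
  jk_above <- rev(cumsum(rev(w$winner == "jackknife")))
  score <- c(jk_above, 0) + c(0, chao_below)  # cut before position i
  cut_at <- which.max(score) - 1L             # number of cells below the cut
  boundary <- if (cut_at == 0 || cut_at == nrow(w)) NA_real_
              else (w$cv[cut_at] + w$cv[cut_at + 1L]) / 2
  list(boundary = boundary, winners = winners)
}

#' Estimate the SAD coefficient of variation from a sample
#'
#' Population-convention standard deviation over mean of the observed
#' per-species counts (detected species only).
#'
#' @param sample an [abundance_sample()] with at least 2 observed species.
#' @return the estimated CV.
#' @export
estimate_cv_from_sample <- function(sample) {
  stopifnot(inherits(sample, "abundance_sample"))
  if (sample$s_obs < 2)
    stop("at least 2 observed species are required to estimate the CV")
  cv_pop(as.numeric(sample$counts))
}

#' Estimator recommendation for a single abundance sample
#'
#' The decision rule: communities with estimated CV above 0.65 (many rare
#' species) use the incidence-Jackknife branch, those below use the Chao
#' branch (a CV of exactly 0.65 falls to the Chao branch, with a note).
#' Within the branch, if the sample's `n/s_obs` exceeds the fitted critical
#' ratio `(n/s)_C` at `(cv_hat, N_hat)`, the split incidence estimator
#' (Chao2 or Jackknife1i/2i on 2-split samples) is recommended; otherwise
#' the single-sample abundance estimator (Chao1 or Jackknife1a).
#'
#' @param n sample size.
#' @param s_obs observed richness.
#' @param N_hat estimated population abundance.
#' @param cv_hat estimated coefficient of variation.
#' @param models named list of `threshold_model`s with elements `chao`
#'   (pair chao2_vs_chao1) and `jackknife` (pair jk_i_vs_jk1a).
#' @return list with `branch`, `use_split`, `estimator`, `threshold`,
#'   `ratio` (= `n/s_obs`), `cv_hat`, `N_hat`, and `note`.
#' @export
recommend <- function(n, s_obs, N_hat, cv_hat, models) {
  stopifnot(n > 0, s_obs > 0, N_hat > 0, cv_hat > 0)
  note <- character()
  if (cv_hat == 0.65) {
    note <- "cv_hat exactly 0.65: tie broken toward the Chao branch"
    message(note)
  }
  branch <- if (cv_hat > 0.65) "jackknife" else "chao"
  model <- models[[branch]]
  if (is.null(model)) stop("`models` must contain a `", branch, "` model")
  if (N_hat < model$N_range[1] || N_hat > model$N_range[2])
    note <- c(note, "N_hat outside the fitted N range; extrapolating")
  threshold <- predict_critical_ratio(model, cv_hat)
  ratio <- n / s_obs
  use_split <- ratio > threshold
  estimator <- if (branch == "jackknife") {
    if (use_split) "jk1i/2i (k = 2 splits)" else "jk1a (single sample)"
  } else {
    if (use_split) "chao2_bc (k = 2 splits)" else "chao1_bc (single sample)"
  }
  list(branch = branch, use_split = use_split, estimator = estimator,
       threshold = threshold, ratio = ratio, cv_hat = cv_hat,
       N_hat = N_hat, note = if (length(note)) note else NULL)
}

#' Write a threshold model to a key-value text file
#'
#' @param model a `threshold_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_threshold_model <- function(model, path) {
  stopifnot(inherits(model, "threshold_model"))
  lines <- c(paste0("pair\t", model$pair),
             paste0("criterion\t", model$criterion),
             paste0("N_low\t", format(model$N_range[1], digits = 15)),
             paste0("N_high\t", format(model$N_range[2], digits = 15)),
             paste0("a\t", format(model$a, digits = 15)),
             paste0("b\t", format(model$b, digits = 15)))
  if (!is.null(model$poly_N))
    lines <- c(lines, paste0("poly_N\t",
                             paste(format(model$poly_N, digits = 15),
                                   collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a threshold model written by [write_threshold_model()]
#'
#' @param path input path.
#' @return a `threshold_model` (without fit points).
#' @export
read_threshold_model <- function(path) {
  kv <- utils::read.delim(path, header = FALSE,
                          col.names = c("key", "value"),
                          colClasses = "character")
  get <- function(k) kv$value[match(k, kv$key)]
  poly <- get("poly_N")
  structure(list(pair = get("pair"), criterion = get("criterion"),
                 N_range = c(as.numeric(get("N_low")),
                             as.numeric(get("N_high"))),
                 a = as.numeric(get("a")), b = as.numeric(get("b")),
                 fit_points = data.frame(cv = numeric(),
                                         critical_ratio = numeric()),
                 poly_N = if (is.na(poly)) NULL else
                   as.numeric(strsplit(poly, ",")[[1]])),
            class = "threshold_model")
}
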
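test_that("lognormal moment derivation matches the closed form and round-trips", {
  # zero-variance limit
  d <- lognormal_derived(1000, 1e-9)
  expect_equal(d[["sigma"]], 0, tolerance = 1e-8)
  expect_equal(d[["mu"]], log(1000), tolerance = 1e-8)
  # hand-evaluated closed form at mean = 1, cv = 1
  d <- lognormal_derived(1, 1)
  expect_equal(d[["sigma"]], sqrt(log(2)), tolerance = 1e-12)
  expect_equal(d[["mu"]], -log(2) / 2, tolerance = 1e-12)
  # lognormal mean identity for a grid of inputs
  for (m in c(0.5, 10, 1000)) for (cv in c(0.15, 0.65, 1.15)) {
    d <- lognormal_derived(m, cv)
    expect_equal(exp(d[["mu"]] + d[["sigma"]]^2 / 2), m, tolerance = 1e-12)
  }
  expect_error(lognormal_derived(-1, 0.5), "positive")
})

test_that("lognormal ranked weights: flat limit, symmetry, bisection oracle", {
  expect_equal(lognormal_ranked_weights(7, 0), rep(1, 7))
  # midpoint-quantile symmetry: w_i * w_{S+1-i} = 1 (erfinv is odd)
  for (S in c(3, 10, 61)) for (sigma in c(0.3, 1, 2)) {
    w <- lognormal_ranked_weights(S, sigma)
    expect_false(is.unsorted(rev(w)))
    expect_equal(w * rev(w), rep(1, S), tolerance = 1e-10)
  }
  # S = 3, sigma = 1, quantiles (1/6, 1/2, 5/6): middle weight exactly 1,
  # outer weight exp(sqrt(2) * erfinv(2/3)) frozen from a bisection on
  # erf(z) = (2/sqrt(pi)) integral exp(-t^2)
  w <- lognormal_ranked_weights(3, 1)
  expect_equal(w[2], 1, tolerance = 1e-12)
  expect_equal(w[1], 2.631151455358, tolerance = 1e-8)
  expect_equal(w[1] * w[3], 1, tolerance = 1e-12)
})

test_that("ranked weights match numerical inversion of the lognormal CDF", {
  # brute-force bisection on the lognormal species-accumulation CDF
  for (S in c(4, 10)) for (sigma in c(0.5, 1.5)) {
    w <- lognormal_ranked_weights(S, sigma)
    oracle <- vapply(seq_len(S), function(i) {
      p <- (i - 0.5) / S  # fraction of species at least this common
      lo <- -50; hi <- 50
      for (it in 1:200) {
        mid <- (lo + hi) / 2
        # P(log weight <= mid) under Normal(0, sigma), counting from common
        if (pnorm(-mid / sigma) < p) hi <- mid else lo <- mid
      }
      exp((lo + hi) / 2)
    }, numeric(1))
    expect_equal(w, oracle, tolerance = 1e-8)
  }
})

test_that("catch probabilities are normalized, ranked, and cover the families", {
  # even community limit
  p <- catch_probabilities(sad_params("lognormal", 12, 50, 1e-9))
  expect_equal(p$probs, rep(1 / 12, 12), tolerance = 1e-6)
  # geometric S = 2, x = 0.5: weights (1, 0.5) normalized
  g <- catch_probabilities(sad_params("geometric", 2, 100, 1 / 3))
  expect_equal(g$probs, c(2 / 3, 1 / 3), tolerance = 1e-6)
  set.seed(42)
  for (fam in c("lognormal", "geometric", "log_series", "negative_binomial")) {
    for (cv in c(0.35, 0.95)) {
      a <- catch_probabilities(sad_params(fam, 15, 200, cv))
      expect_equal(sum(a$probs), 1, tolerance = 1e-12)
      expect_false(is.unsorted(rev(a$probs)))
      expect_true(all(a$probs > 0))
      expect_equal(a$cumprobs[15], 1, tolerance = 1e-12)
      expect_false(is.unsorted(a$cumprobs))
      expect_equal(sum(a$abundances), a$params$N, tolerance = 1e-9)
    }
  }
  expect_error(sad_params("lognormal", 0, 100, 0.5), "positive integer")
})

test_that("series parameter solving hits the requested CV and flags infeasibility", {
  # negative binomial closed form: mean 10, cv 1 -> var 100, r = 100/90, p = 0.1
  nb <- series_params_from_cv("negative_binomial", 10, 10, 1)
  expect_equal(nb$r, 100 / 90, tolerance = 1e-12)
  expect_equal(nb$p, 0.1, tolerance = 1e-12)
  # geometric S = 2: cv of (1, x) is (1-x)/(1+x); cv = 1/3 gives x = 0.5
  geo <- series_params_from_cv("geometric", 2, 100, 1 / 3)
  expect_equal(geo$x, 0.5, tolerance = 1e-6)
  # brute-force scan oracle for the same root
  xs <- seq(0.01, 0.99, by = 1e-4)
  cv_scan <- (1 - xs) / (1 + xs)
  expect_equal(geo$x, xs[which.min(abs(cv_scan - 1 / 3))], tolerance = 1e-3)
  # even-community limit: x -> 1
  expect_gt(series_params_from_cv("geometric", 5, 100, 1e-9)$x, 0.999)
  # solved families reproduce the cv in their ranked weights
  for (fam in c("geometric", "log_series")) for (cv in c(0.3, 0.9)) {
    a <- catch_probabilities(sad_params(fam, 12, 100, cv))
    w <- a$probs
    m <- mean(w)
    expect_equal(sqrt(mean((w - m)^2)) / m, cv, tolerance = 1e-5)
  }
  # unattainable cv errors name the range
  expect_error(series_params_from_cv("geometric", 2, 100, 1.2), "attainable")
  expect_error(series_params_from_cv("negative_binomial", 5, 4, 0.1),
               "variance > mean")
})

test_that("commonest species' share increases with dispersion", {
  for (fam in c("lognormal", "geometric")) {
    top <- vapply(seq(0.2, 1.1, by = 0.15), function(cv)
      catch_probabilities(sad_params(fam, 25, 100, cv))$probs[1], numeric(1))
    expect_true(all(diff(top) > 0))
  }
})

test_that("assemblage TSV round-trips", {
  a <- catch_probabilities(sad_params("lognormal", 9, 120, 0.7))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_assemblage(a, path)
  b <- read_assemblage(path)
  expect_equal(b$probs, a$probs, tolerance = 1e-12)
  expect_equal(b$abundances, a$abundances, tolerance = 1e-9)
  expect_equal(b$params$N, a$params$N, tolerance = 1e-6)
})
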
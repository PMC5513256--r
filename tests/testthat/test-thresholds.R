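test_that("critical_ratio finds a constructed crossing and handles the boundaries", {
  set.seed(1)
  n_over_s <- runif(400, 1, 60)
  # negative proportionate difference exactly above n/s = 30
  pd <- ifelse(n_over_s > 30, -abs(rnorm(400)), abs(rnorm(400)))
  cr <- critical_ratio(n_over_s, pd, "mid")
  expect_true(cr$crossed)
  # the located bin midpoint sits within one bin width of the true point
  widths <- diff(quantile(n_over_s, seq(0, 1, 0.1)))
  expect_lt(abs(cr$value - 30), max(widths))
  # all negative: lowest bin midpoint
  cr_all <- critical_ratio(n_over_s, rep(-1, 400), "mid")
  expect_true(cr_all$crossed)
  expect_equal(cr_all$value, cr_all$bins$midpoint[1])
  # all positive: sentinel, not an exception
  cr_none <- critical_ratio(n_over_s, rep(1, 400), "mid")
  expect_false(cr_none$crossed)
  expect_true(is.na(cr_none$value))
  # edge criterion demands near-unanimity
  pd_mixed <- ifelse(n_over_s > 30, ifelse(runif(400) < 0.7, -1, 1), 1)
  expect_false(critical_ratio(n_over_s, pd_mixed, "edge")$crossed)
  expect_error(critical_ratio(1:5, rep(-1, 5)), "20")
})

test_that("power-law fitting recovers noiseless curves exactly", {
  cv <- seq(0.25, 1.15, by = 0.1)
  pts <- data.frame(cv = cv, critical_ratio = 80.10 * cv^2.05)
  fit <- fit_power_law(pts)
  expect_equal(fit$a, 80.10, tolerance = 1e-6)
  expect_equal(fit$b, 2.05, tolerance = 1e-6)
  # flat points: exponent ~ 0
  flat <- fit_power_law(data.frame(cv = cv, critical_ratio = rep(7, 10)))
  expect_equal(flat$b, 0, tolerance = 1e-6)
  expect_equal(flat$a, 7, tolerance = 1e-6)
  # brute-force grid-search oracle agrees to grid resolution
  pts2 <- data.frame(cv = cv, critical_ratio = 29.22 * cv^3.16)
  fit2 <- fit_power_law(pts2)
  grid <- expand.grid(a = seq(20, 40, 0.2), b = seq(2, 4, 0.02))
  sse <- mapply(function(a, b) sum((pts2$critical_ratio - a * pts2$cv^b)^2),
                grid$a, grid$b)
  best <- grid[which.min(sse), ]
  expect_lt(abs(fit2$a - best$a), 0.2)
  expect_lt(abs(fit2$b - best$b), 0.02)
  expect_error(fit_power_law(data.frame(cv = c(1, 2), critical_ratio = c(1, 2))),
               "3 points")
})

test_that("noisy power-law points are recovered within the stochastic band", {
  cv <- seq(0.25, 1.15, by = 0.1)
  truth <- 80.10 * cv^2.05
  set.seed(9)
  ok_a <- ok_b <- logical(100)
  for (i in 1:100) {
    pts <- data.frame(cv = cv,
                      critical_ratio = truth * runif(10, 0.9, 1.1))
    fit <- fit_power_law(pts)
    ok_a[i] <- abs(fit$a - 80.10) / 80.10 < 0.15
    ok_b[i] <- abs(fit$b - 2.05) < 0.3
  }
  expect_gt(mean(ok_a), 0.95)
  expect_gt(mean(ok_b), 0.95)
})

test_that("cubic N-dependence fit interpolates and matches the normal equations", {
  N <- c(1e3, 5e3, 2e4, 1e5)
  r <- 2 - 1e-3 * N + 3e-8 * N^2 - 1e-13 * N^3
  cf <- fit_poly_N(data.frame(N = N, critical_ratio = r))
  expect_equal(unname(cf), c(2, -1e-3, 3e-8, -1e-13), tolerance = 1e-6)
  # constant points: higher coefficients vanish
  cf0 <- fit_poly_N(data.frame(N = c(N, 2e5), critical_ratio = rep(4, 5)))
  expect_equal(unname(cf0), c(4, 0, 0, 0), tolerance = 1e-9)
  # normal-equations oracle on an overdetermined system (N rescaled to keep
  # the oracle's explicit normal equations well conditioned)
  set.seed(3)
  N2 <- seq(1, 10, length.out = 12)
  r2 <- 5 + 2 * N2 + rnorm(12)
  X <- cbind(1, N2, N2^2, N2^3)
  beta <- solve(t(X) %*% X, t(X) %*% r2)
  cf2 <- fit_poly_N(data.frame(N = N2, critical_ratio = r2))
  expect_equal(unname(cf2), as.vector(beta), tolerance = 1e-6)
})

test_that("sample CV estimation uses the population convention", {
  expect_equal(estimate_cv_from_sample(abundance_sample(c(4, 4, 4))), 0)
  expect_equal(estimate_cv_from_sample(abundance_sample(c(1, 3))), 0.5)
  expect_error(estimate_cv_from_sample(abundance_sample(c(5))), "2 observed")
  # rank correlation with the generating cv across a grid
  cvs <- seq(0.2, 1.1, by = 0.15)
  set.seed(13)
  cv_hat <- vapply(cvs, function(cv) {
    a <- catch_probabilities(sad_params("lognormal", 30, 200, cv))
    mean(vapply(1:8, function(i)
      estimate_cv_from_sample(draw_sample(a, 2000)), numeric(1)))
  }, numeric(1))
  expect_gt(cor(cvs, cv_hat, method = "spearman"), 0.9)
})

test_that("the recommendation rule dispatches on CV and the fitted threshold", {
  mk <- function(pair, a, b) structure(
    list(pair = pair, criterion = "mid", N_range = c(1e3, 1e5),
         a = a, b = b,
         fit_points = data.frame(cv = 1, critical_ratio = a)),
    class = "threshold_model")
  models <- list(chao = mk("chao2_vs_chao1", 80.10, 2.05),
                 jackknife = mk("jk_i_vs_jk1a", 29.22, 3.16))
  # high cv, far above threshold: split jackknife
  r <- recommend(n = 5000, s_obs = 50, N_hat = 2e4, cv_hat = 0.95, models)
  expect_identical(r$branch, "jackknife")
  expect_true(r$use_split)
  expect_match(r$estimator, "jk1i/2i")
  expect_equal(r$threshold, 29.22 * 0.95^3.16, tolerance = 1e-9)
  # low cv, far above threshold: split chao2
  r <- recommend(n = 5000, s_obs = 50, N_hat = 2e4, cv_hat = 0.35, models)
  expect_identical(r$branch, "chao")
  expect_true(r$use_split)
  expect_match(r$estimator, "chao2")
  # below threshold at high cv: single-sample jackknife
  r <- recommend(n = 300, s_obs = 60, N_hat = 2e4, cv_hat = 0.95, models)
  expect_false(r$use_split)
  expect_match(r$estimator, "jk1a")
  # tie at 0.65 goes to the chao branch with a note
  expect_message(r <- recommend(1000, 30, 1e4, 0.65, models), "0.65")
  expect_identical(r$branch, "chao")
})

test_that("threshold models serialize and round-trip", {
  m <- structure(list(pair = "jk_i_vs_jk1a", criterion = "mid",
                      N_range = c(1e3, 1e5), a = 29.22, b = 3.16,
                      fit_points = data.frame(cv = 1, critical_ratio = 29.22),
                      poly_N = c(1, 2e-4, 0, 0)),
                 class = "threshold_model")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_threshold_model(m, path)
  m2 <- read_threshold_model(path)
  expect_equal(m2$a, m$a)
  expect_equal(m2$b, m$b)
  expect_identical(m2$pair, m$pair)
  expect_equal(m2$N_range, m$N_range)
  expect_equal(m2$poly_N, m$poly_N)
  expect_equal(predict_critical_ratio(m2, 0.8), 29.22 * 0.8^3.16)
})
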
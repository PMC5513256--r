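test_that("Chao estimators reproduce hand-evaluated values and vanish without rares", {
  # counts {1,1,1,2,2,5}: s = 6, n = 12, f1 = 3, f2 = 2
  s <- abundance_sample(c(1, 1, 1, 2, 2, 5))
  expect_equal(chao1_bc(s)$estimate, 6 + (11 / 12) * 6 / 6, tolerance = 1e-12)
  # no singletons: correction vanishes
  expect_equal(chao1_bc(abundance_sample(c(2, 3, 4)))$estimate, 3)
  # incidence: m = 2, s = 5, q1 = 2, q2 = 3 -> 5.125
  mat <- rbind(c(1, 0), c(0, 1), c(1, 1), c(1, 1), c(1, 1))
  expect_equal(chao2_bc(incidence_set(mat))$estimate, 5.125, tolerance = 1e-12)
  q0 <- incidence_set(rbind(c(1, 1), c(1, 1)))
  expect_equal(chao2_bc(q0)$estimate, 2)
})

test_that("jackknife estimators reproduce hand values; orders coincide at m = 2", {
  s <- abundance_sample(c(1, 1, 1, 2, 2, 5))
  expect_equal(jackknife_abundance(s, 1)$estimate, 6 + 3 * 11 / 12,
               tolerance = 1e-12)
  expect_equal(jackknife_abundance(s, 2)$estimate,
               6 + 3 * 21 / 12 - 2 * 100 / 132, tolerance = 1e-12)
  expect_equal(jackknife_abundance(abundance_sample(c(3, 3)), 1)$estimate, 2)
  # m = 2, s = 8, q1 = 4 -> jk1i = 10
  inc <- incidence_set(rbind(c(1, 0), c(0, 1), c(1, 0), c(0, 1),
                             matrix(1, 4, 2)))
  expect_equal(jackknife_incidence(inc, 1)$estimate, 10, tolerance = 1e-12)
  # the (m-2)^2 term vanishes at m = 2: both orders identical, on 1000 sets
  set.seed(3)
  for (i in 1:1000) {
    r <- random_incidence(m = 2, s_max = 25)
    expect_identical(jackknife_incidence(r, 1)$estimate,
                     jackknife_incidence(r, 2)$estimate)
  }
})

test_that("ACE reproduces hand values and handles its branches", {
  # counts {1,1,2,3,15}: C = 5/7, gamma2 = 1/15 -> 6.786667
  a <- ace(abundance_sample(c(1, 1, 2, 3, 15)))
  expect_equal(a$estimate, 1 + 5.6 + 2.8 * (5.6 * 8 / 42 - 1),
               tolerance = 1e-9)
  # no rare species at all
  expect_equal(ace(abundance_sample(c(20, 30)))$estimate, 2)
  # f1 = 0, all rare counts 2: gamma2 = 0 branch, estimate = S_rare/C
  b <- ace(abundance_sample(c(2, 2, 2)))
  expect_equal(b$estimate, 3, tolerance = 1e-12)
  expect_equal(b$inputs$gamma2, 0)
  # all-singleton rare class: zero coverage falls back to chao1 with warning
  expect_warning(fb <- ace(abundance_sample(c(1, 1, 1))), "chao1")
  expect_true(fb$fallback)
  expect_equal(fb$estimate, chao1_bc(abundance_sample(c(1, 1, 1)))$estimate)
})

test_that("ICE matches a direct evaluation of its formula and falls back at zero coverage", {
  # m = 2, s = 6, q1 = 2, q2 = 4
  mat <- rbind(c(1, 0), c(0, 1), c(1, 1), c(1, 1), c(1, 1), c(1, 1))
  inc <- incidence_set(mat)
  q1 <- 2; q2 <- 4; s <- 6; n_inf <- q1 + 2 * q2; m_inf <- 2
  C <- 1 - q1 / n_inf
  g2 <- max(s / C * (m_inf / (m_inf - 1)) * (2 * q2) / n_inf^2 - 1, 0)
  expect_equal(ice(inc)$estimate, s / C + q1 / C * g2, tolerance = 1e-12)
  # every species in both sub-samples: estimate = s_obs
  allboth <- incidence_set(matrix(1, 4, 2))
  expect_equal(ice(allboth)$estimate, 4)
  # all species in exactly one sub-sample: coverage 0 -> chao2 fallback
  single <- incidence_set(rbind(c(1, 0), c(0, 1), c(1, 0)))
  expect_warning(fb <- ice(single), "chao2")
  expect_true(fb$fallback)
})

test_that("every estimator is bounded below by the observed richness", {
  set.seed(17)
  for (i in 1:300) {
    s <- random_counts()
    expect_gte(chao1_bc(s)$estimate, s$s_obs)
    expect_gte(jackknife_abundance(s, 1)$estimate, s$s_obs)
    expect_gte(jackknife_abundance(s, 2)$estimate, s$s_obs)
    expect_gte(suppressWarnings(ace(s)$estimate), s$s_obs)
    r <- random_incidence(m = sample(2:4, 1))
    expect_gte(chao2_bc(r)$estimate, r$s_obs)
    expect_gte(jackknife_incidence(r, 1)$estimate, r$s_obs)
    expect_gte(jackknife_incidence(r, 2)$estimate, r$s_obs)
    expect_gte(suppressWarnings(ice(r)$estimate), r$s_obs)
  }
})

test_that("chao1_bc and ACE agree with the established implementation (vegan)", {
  set.seed(23)
  for (i in 1:100) {
    s <- random_counts(s_max = 60, lambda = sample(1:6, 1))
    v <- suppressWarnings(vegan::estimateR(as.integer(s$counts)))
    # vegan's chao1 omits the (n-1)/n small-sample factor; apply it to the
    # oracle's correction term before comparing
    oracle_chao1 <- s$s_obs + (s$n - 1) / s$n * (v[["S.chao1"]] - s$s_obs)
    expect_equal(chao1_bc(s)$estimate, oracle_chao1, tolerance = 1e-9)
    expect_equal(suppressWarnings(ace(s)$estimate), v[["S.ACE"]],
                 tolerance = 1e-9)
  }
})

test_that("adding an individual of an abundant species perturbs chao1 by O(1/n)", {
  s <- abundance_sample(c(1, 1, 1, 2, 2, 50))
  s2 <- abundance_sample(c(1, 1, 1, 2, 2, 51))
  expect_lt(abs(chao1_bc(s2)$estimate - chao1_bc(s)$estimate), 5 / s$n)
})

test_that("in the coupon-collector regime every estimator returns S exactly", {
  a <- catch_probabilities(sad_params("lognormal", 10, 1000, 1e-9))
  s <- draw_sample(a, 2000, seed = 31)
  expect_true(all(s$counts > 2))
  for (est in list(chao1_bc(s), jackknife_abundance(s, 1),
                   jackknife_abundance(s, 2), ace(s)))
    expect_equal(est$estimate, 10)
  se <- split_estimate(s, "chao2_bc", n_splits = 10, seed = 32)
  expect_identical(se$aggregate, 10)
})
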
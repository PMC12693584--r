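test_that("poisson_loglik evaluates the composite likelihood", {
  obs <- sfs(c(0, 2, 1, 0))
  good <- sfs(c(0, 2, 1, 0))
  bad <- sfs(c(0, 1, 2, 0))
  ll_good <- poisson_loglik(good, obs)
  ll_bad <- poisson_loglik(bad, obs)
  hand <- function(m) sum(c(2, 1) * log(m) - m - lfactorial(c(2, 1)))
  expect_equal(ll_good, hand(c(2, 1)))
  expect_equal(ll_bad, hand(c(1, 2)))
  expect_gt(ll_good, ll_bad)

  # the likelihood is maximal at expected = observed among all scalings
  for (c0 in c(0.3, 0.9, 2, 5)) {
    scaled <- sfs(good$counts * c0)
    expect_lte(poisson_loglik(scaled, obs), ll_good)
  }
  # profiled multiplier has the closed form sum(obs)/sum(exp)
  prof <- poisson_loglik(good, sfs(c(0, 4, 2, 0)), profile_theta = TRUE)
  expect_equal(prof$multiplier, 2)
  expect_equal(poisson_loglik(sfs(c(0, 0, 1, 0)), obs), -Inf)
})

test_that("one-epoch fit profiles theta exactly", {
  obs <- expected_sfs_equilibrium(40, theta = 123)
  f <- fit_demography(obs, "one_epoch", mu = 1e-8, L_s = 123 / (4e-8 * 1e4))
  expect_equal(f$theta, 123, tolerance = 1e-6)
  expect_equal(f$N_a, 1e4, tolerance = 1e-6)
})

test_that("two-epoch parameters are recovered from noiseless spectra", {
  truth <- expected_sfs_two_epoch(60, theta = 4000, nu = 2, T = 0.05)
  f <- fit_demography(truth, "two_epoch", n_starts = 15, seed = 21)
  expect_equal(f$nu, 2, tolerance = 0.02)
  expect_equal(f$T, 0.05, tolerance = 0.02)
  expect_equal(f$theta, 4000, tolerance = 0.02)
  expect_true(f$converged)
  expect_false(any(f$at_bounds))
  # the fast grid-scan method lands on the same optimum
  g <- fit_demography(truth, "two_epoch", method = "grid")
  expect_equal(g$nu, 2, tolerance = 0.02)
  expect_equal(g$T, 0.05, tolerance = 0.02)
})

test_that("neutral data do not support the two-epoch model", {
  obs <- expected_sfs_equilibrium(60, theta = 2000)
  f1 <- fit_demography(obs, "one_epoch")
  f2 <- fit_demography(obs, "two_epoch", n_starts = 10, seed = 5)
  expect_lt(f2$loglik - f1$loglik, 3)
  chosen <- select_model_lrt(f1, f2)
  expect_equal(chosen$model, "one_epoch")
})

test_that("spectra from pervasive strong selection drive fits to bounds", {
  # synonymous spectrum under gamma = -10 (s = 1e-3 at N = 10,000, additive)
  obs <- expected_sfs_equilibrium(60, theta = 2000, gamma = -10)
  f2 <- fit_demography(obs, "two_epoch", n_starts = 15, seed = 31)
  expect_true(any(f2$at_bounds))
  expect_gt(f2$nu, 1)  # interpreted as an (extreme) expansion
})

test_that("the likelihood-ratio rule uses the delta-LL threshold of 3", {
  obs <- expected_sfs_equilibrium(30, theta = 500)
  f1 <- fit_demography(obs, "one_epoch")
  f2 <- fit_demography(obs, "two_epoch", n_starts = 5, seed = 1)
  # half the chi-squared(2 df) 95th percentile rounds to the threshold
  expect_equal(round(qchisq(0.95, df = 2) / 2), 3)
  for (dll in c(3.5, 2.9, 0)) {
    f2x <- f2
    f2x$loglik <- f1$loglik + dll
    chosen <- select_model_lrt(f1, f2x)
    expect_equal(chosen$model, if (dll > 3) "two_epoch" else "one_epoch")
    expect_equal(chosen$delta_ll, dll)
  }
  other <- fit_demography(expected_sfs_equilibrium(30, 600), "one_epoch")
  expect_error(select_model_lrt(other, f2), "different observed")
})

test_that("ancestral size inverts theta_s = 4 N mu L", {
  expect_equal(ancestral_N(4 * 1e4 * 1.5e-8 * 9.7e6, 1.5e-8, 9.7e6), 1e4)
  # theta near 1.5 over ~10 Mb of synonymous sequence implies N_a of
  # a few individuals — the degenerate regime reached at the nu bound
  expect_lt(ancestral_N(1.5, 1.5e-8, 9.7e6), 5)
  expect_error(ancestral_N(0, 1e-8, 1e6), "positive")
})

test_that("Poisson-noise parameter recovery is unbiased at 30 Mb scale", {
  # theta_s for ~30 Mb of coding sequence (9 Mb synonymous): ~5400
  truth <- expected_sfs_two_epoch(60, theta = 5400, nu = 2, T = 0.05)
  m <- polymorphic(truth)
  nus <- Ts <- numeric(25)
  for (k in 1:25) {
    counts <- numeric(61)
    counts[2:60] <- withr::with_seed(600 + k, rpois(59, m))
    f <- fit_demography(sfs(counts), "two_epoch", method = "grid")
    nus[k] <- f$nu; Ts[k] <- f$T
  }
  expect_lt(abs(mean(nus) - 2), 3 * stats::sd(nus) / 5 + 0.02)
  expect_lt(abs(mean(Ts) - 0.05), 3 * stats::sd(Ts) / 5 + 0.002)
})

test_that("fit objects expose tidy and glance summaries", {
  obs <- expected_sfs_equilibrium(30, theta = 500)
  f <- fit_demography(obs, "one_epoch", mu = 1e-8, L_s = 1e6)
  td <- tidy(f)
  expect_named(td, c("term", "estimate", "at_bound"))
  gl <- glance(f)
  expect_equal(gl$model, "one_epoch")
  expect_true(is.finite(gl$loglik))
})
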
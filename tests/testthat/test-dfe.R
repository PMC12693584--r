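fit_neutral_demog <- function(n = 60, theta = 1000) {
  obs <- expected_sfs_equilibrium(n, theta = theta)
  fit_demography(obs, "one_epoch", mu = 1.5e-7,
                 L_s = theta / (4 * 1000 * 1.5e-7))
}

test_that("the gamma grid cache has the promised structure", {
  f <- fit_neutral_demog()
  cache <- build_gamma_cache(f)
  expect_equal(cache$gammas[1], 0)
  expect_true(all(diff(cache$gammas) > 0))
  expect_gte(max(cache$gammas), 2000)
  expect_lte(cache$gammas[2], 1e-4)
  # the grid covers the mean of the generating DFE, |gamma| ~ 131
  expect_true(any(cache$gammas > 131) && any(cache$gammas < 131))
  # neutral endpoint equals the demography-only expectation
  expect_equal(cache$spectra[1, ],
               polymorphic(expected_sfs(f, gamma = 0, theta = 1)),
               tolerance = 1e-10)
  # total polymorphic mass decreases with selection strength
  mass <- rowSums(cache$spectra)
  expect_true(all(diff(mass) < 0))
  expect_error(build_gamma_cache(f, gamma_range = c(1, 100)), "span")
})

test_that("the DFE mixture is linear in theta and exact in limits", {
  f <- fit_neutral_demog()
  cache <- build_gamma_cache(f)
  a <- expected_sfs_under_dfe(cache, 0.186, 706.899, theta_ns = 1)
  b <- expected_sfs_under_dfe(cache, 0.186, 706.899, theta_ns = 2)
  expect_equal(b$counts, 2 * a$counts, tolerance = 1e-12)
  # integration weights are a probability mass function
  w <- syndfe:::gamma_grid_weights(cache$gammas, 0.186, 706.899)
  expect_equal(sum(w), 1, tolerance = 1e-9)
  expect_true(all(w >= 0))
  # a near-point-mass gamma at a grid point reproduces that cached row
  g0 <- cache$gammas[40]
  pm <- expected_sfs_under_dfe(cache, shape = 5000,
                               scale_gamma = g0 / 5000, theta_ns = 1)
  expect_equal(polymorphic(pm), cache$spectra[40, ], tolerance = 0.01)
  expect_error(expected_sfs_under_dfe(cache, -1, 10, 1), "positive")
})

test_that("halving the gamma grid barely changes the mixture", {
  f <- fit_neutral_demog()
  fine <- build_gamma_cache(f)
  coarse <- build_gamma_cache(f, n_grid = 41L)
  a <- polymorphic(expected_sfs_under_dfe(fine, 0.186, 706.899, 100))
  b <- polymorphic(expected_sfs_under_dfe(coarse, 0.186, 706.899, 100))
  expect_lt(max(abs(b / a - 1)), 0.002)
})

test_that("gamma DFE parameters are recovered from noiseless spectra", {
  f <- fit_neutral_demog(n = 100, theta = 560)
  cache <- build_gamma_cache(f)
  theta_ns <- 2.31 * f$theta
  for (par in list(c(0.186, 706.899), c(0.4, 50), c(1, 2000))) {
    obs <- expected_sfs_under_dfe(cache, par[1], par[2], theta_ns)
    d <- fit_dfe(obs, cache, theta_ns, n_starts = 10, seed = 17)
    expect_equal(d$shape, par[1], tolerance = 0.01)
    expect_equal(d$scale_gamma, par[2], tolerance = 0.01)
  }
})

test_that("DFE recovery under Poisson noise is unbiased at 30 Mb scale", {
  # theta_ns ~ 2.31 * theta_s with theta_s ~ 5400 (about 30 Mb coding)
  f <- fit_neutral_demog(n = 60, theta = 5400)
  cache <- build_gamma_cache(f)
  theta_ns <- 2.31 * 5400
  truth <- polymorphic(expected_sfs_under_dfe(cache, 0.186, 706.899,
                                              theta_ns))
  shapes <- scales <- numeric(20)
  for (k in 1:20) {
    counts <- numeric(61)
    counts[2:60] <- withr::with_seed(900 + k, rpois(59, truth))
    d <- fit_dfe(sfs(counts), cache, theta_ns, n_starts = 8,
                 seed = 30 + k)
    shapes[k] <- d$shape; scales[k] <- d$scale_gamma
  }
  expect_lt(abs(mean(shapes) - 0.186),
            3 * stats::sd(shapes) / sqrt(20) + 0.002)
  expect_lt(abs(mean(log(scales)) - log(706.899)),
            3 * stats::sd(log(scales)) / sqrt(20) + 0.02)
})

test_that("scale conversion to heterozygous units divides by 2 N_a", {
  expect_equal(scale_to_s(706.899, 8079), 0.04375, tolerance = 1e-3)
  expect_equal(scale_to_s(706.899, 10000), 0.03534, tolerance = 1e-3)
  expect_equal(scale_to_s(0, 5000), 0)
  expect_error(scale_to_s(10, 0), "positive")
})

test_that("discretization masses are exact and match Monte Carlo", {
  d <- discretize_dfe(0.186, 0.04375)
  expect_equal(sum(d$mass), 1, tolerance = 1e-9)
  expect_equal(nrow(d), 5)
  expect_equal(d$lower, c(0, 1e-5, 1e-4, 1e-3, 1e-2))
  mc <- discretize_dfe(0.186, 0.04375, method = "mc", n_draws = 1e6,
                       seed = 4)
  expect_equal(mc$mass, d$mass, tolerance = 0.01)
  # a sharp gamma with mean inside one bin puts all mass there
  sharp <- discretize_dfe(1e4, 3e-4 / 1e4)
  expect_equal(sharp$mass[3], 1, tolerance = 1e-6)
  expect_error(discretize_dfe(0.2, 0.1, edges = c(0, 1, 0.5, Inf)),
               "increasing")
})

test_that("standardized residuals follow their definition", {
  tru <- c(0.25, 0.16, 0.2, 0.19, 0.2)
  expect_equal(standardized_residuals(tru, tru), rep(0, 5))
  inf <- tru + c(0.04, -0.04, 0, 0, 0)
  r <- standardized_residuals(inf, tru)
  expect_equal(r[1], 0.04 / sqrt(0.25))
  expect_equal(r[2], -0.04 / sqrt(0.16))
  expect_equal(standardized_residuals(tru + 0.01, tru),
               -standardized_residuals(tru - 0.01, tru))
  expect_error(standardized_residuals(1, c(1, 2)), "mismatch")
  expect_error(standardized_residuals(c(1, 0), c(1, 0)), "positive")
})
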
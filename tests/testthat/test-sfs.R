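test_that("tally_sfs bins derived-allele counts correctly", {
  expect_equal(tally_sfs(integer(0), n = 4)$counts, rep(0, 5))
  expect_equal(tally_sfs(c(1, 1, 2), n = 4)$counts, c(0, 2, 1, 0, 0))
  fixed <- tally_sfs(4, n = 4)
  expect_equal(fixed$counts, c(0, 0, 0, 0, 1))
  expect_equal(segregating_sites(fixed), 0)
  expect_error(tally_sfs(5, n = 4), "\\[0, n\\]")
  expect_error(tally_sfs(-1, n = 4), "\\[0, n\\]")
})

test_that("sfs constructor enforces its invariants", {
  expect_error(sfs(c(1, 2), n = 3), "length")
  expect_error(sfs(c(-1, 0, 0)), "non-negative")
  expect_silent(sfs(c(0, 1.5, 0)))  # real-valued expected spectra allowed
})

test_that("pi matches hand-computed and brute-force values", {
  expect_equal(sfs_pi(sfs(rep(0, 5))), 0)
  # n = 4, polymorphic counts (3, 2, 1): (3*3 + 2*4 + 1*3) / 6
  expect_equal(sfs_pi(sfs(c(0, 3, 2, 1, 0))), 10 / 3, tolerance = 1e-12)
  expect_error(sfs_pi(sfs(c(0, 0), n = 1)), "at least 2")

  # property: SFS formula equals mean pairwise difference on explicit
  # haplotype matrices, exactly
  set.seed(42)
  for (k in 1:20) {
    n <- sample(2:10, 1)
    sites <- sample(1:50, 1)
    mat <- matrix(rbinom(sites * n, 1, runif(1, 0.1, 0.9)), nrow = sites)
    x <- tally_sfs(rowSums(mat), n = n)
    expect_equal(sfs_pi(x), brute_force_pi(mat), tolerance = 1e-12)
  }
})

test_that("neutral equilibrium diversity is 4 N mu L per site", {
  # theta = 6e-4 per site is the neutral expectation for N = 10,000 and
  # mu = 1.5e-8; pi of the expected spectrum recovers it exactly
  L <- 1e6
  x <- expected_sfs_equilibrium(40, theta = 6e-4 * L)
  expect_equal(sfs_pi(x) / L, 6e-4, tolerance = 1e-9)
  expect_equal(4 * 10000 * 1.5e-8, 6e-4)
})

test_that("pi_ratio compares observed diversity with 4 N mu L", {
  zero <- sfs(rep(0, 21), L = 100)
  expect_equal(pi_ratio(zero, N = 100, mu = 1e-6)$ratio, 0)
  # exact neutral equilibrium spectrum gives ratio 1
  N <- 500; mu <- 1e-6; L <- 1e5
  x <- expected_sfs_equilibrium(20, theta = 4 * N * mu * L)
  x$L <- L
  out <- pi_ratio(x, N = N, mu = mu)
  expect_equal(out$ratio, 1, tolerance = 1e-9)
  expect_equal(out$pi0, 4 * N * mu * L)
  expect_error(pi_ratio(zero, N = -1, mu = 1e-6), "positive")
})

test_that("sum_sfs adds spectra, lengths, and stays associative", {
  a <- sfs(c(0, 1, 0), L = 10)
  b <- sfs(c(0, 2, 1), L = 5)
  expect_equal(sum_sfs(list(a))$counts, a$counts)
  ab <- sum_sfs(a, b)
  expect_equal(ab$counts, c(0, 3, 1))
  expect_equal(ab$L, 15)
  cc <- sfs(c(1, 4, 2), L = 1)
  expect_equal(sum_sfs(sum_sfs(a, b), cc)$counts,
               sum_sfs(a, sum_sfs(b, cc))$counts)
  expect_equal(sum_sfs(b, a)$counts, ab$counts)
  # pi is additive over summed spectra
  expect_equal(sfs_pi(ab), sfs_pi(a) + sfs_pi(b))
  expect_error(sum_sfs(a, sfs(c(0, 1, 0, 0))), "sample sizes")
  expect_error(sum_sfs(a, fold_sfs(b)), "folding")
})

test_that("22 chunk spectra sum to one replicate spectrum", {
  set.seed(7)
  chunks <- lapply(1:22, function(k) tally_sfs(sample(1:9, 30, TRUE), 10))
  rep_sfs <- sum_sfs(chunks)
  expect_equal(segregating_sites(rep_sfs),
               sum(vapply(chunks, segregating_sites, 0)))
})

test_that("fs round trip is bit-stable and parse errors are located", {
  path <- withr::local_tempfile(fileext = ".fs")
  x <- sfs(c(0, 17, 5, 3, 0), L = 100, class_label = "synonymous")
  write_fs(x, path)
  y <- read_fs(path, L = 100, class_label = "synonymous")
  expect_identical(y$counts, x$counts)
  expect_identical(y$n, x$n)
  expect_identical(y$folded, FALSE)

  # header with n+1 = 101 values means a sample of 100 haploid genomes
  big <- sfs(c(0, rpois(99, 5), 0))
  write_fs(big, path)
  expect_equal(read_fs(path)$n, 100)

  writeLines(c("5 sideways", "0 1 2 1 0", "1 0 0 0 1"), path)
  expect_error(read_fs(path), "folded")
  writeLines(c("5 unfolded", "0 1 2 1", "1 0 0 0 1"), path)
  expect_error(read_fs(path), "expected 5")
})

test_that("folding reflects counts onto minor-allele bins", {
  x <- sfs(c(1, 5, 3, 2, 7))
  f <- fold_sfs(x)
  expect_true(f$folded)
  expect_equal(f$counts, c(8, 7, 3, 0, 0))
  expect_equal(sum(f$counts), sum(x$counts))
})
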
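# small neutral configuration shared by several blocks
tiny_neutral_config <- function(N = 200, L_ex = 5e4) {
  sim_config(N = N, mu = 1.5e-6, r = 1e-6, burn_in = 10 * N,
             extra_generations = 50, sample_n = 50,
             syn_model = selection_model("neutral"),
             ns_model = selection_model("neutral"),
             mean_exon_len = 300, mean_intron_len = 1200,
             target_exonic = L_ex, purge_every = 25)
}

test_that("simulation runs are reproducible given the seed", {
  cfg <- tiny_neutral_config(N = 50, L_ex = 1e4)
  lay <- generate_layout(300, 1200, 1e4, seed = 3)
  a <- simulate_population(cfg, lay, seed = 42)
  b <- simulate_population(cfg, lay, seed = 42)
  expect_identical(a$mutations, b$mutations)
  expect_identical(a$haplotypes, b$haplotypes)
  c1 <- simulate_population(cfg, lay, seed = 43)
  expect_false(identical(a$mutations, c1$mutations))
})

test_that("neutral equilibrium diversity and SFS shape are recovered", {
  cfg <- tiny_neutral_config()
  n_seeds <- 20
  classes <- list(1, 2, 3, 4, 5:9, 10:19, 20:49)
  pis <- numeric(n_seeds)
  props <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    lay <- generate_layout(300, 1200, cfg$target_exonic, seed = s)
    st <- simulate_population(cfg, lay, seed = 500 + s)
    sp <- sample_sfs(st, cfg$sample_n, seed = s)
    tot <- sum_sfs(sp$synonymous, sp$nonsynonymous)
    tot$class_label <- "other"
    pis[s] <- sfs_pi(tot) / cfg$target_exonic
    obs <- polymorphic(tot)
    props[[s]] <- vapply(classes, function(ix) sum(obs[ix]), 0) / sum(obs)
  }
  theta_site <- 4 * cfg$N * cfg$mu
  # per-site diversity within 3 standard errors of 4 N mu
  expect_lt(abs(mean(pis) - theta_site),
            3 * stats::sd(pis) / sqrt(n_seeds))
  # SFS shape vs theta/i: chi-squared over frequency classes, with the
  # between-replicate variance as the error model (linkage makes bins
  # over-dispersed relative to independent Poisson counts)
  classes <- list(1, 2, 3, 4, 5:9, 10:19, 20:49)
  P <- t(vapply(props, function(p) p, numeric(length(classes))))
  pexp <- vapply(classes, function(ix) sum(1 / ix), 0) /
    sum(1 / seq_len(cfg$sample_n - 1))
  z <- (colMeans(P) - pexp) / (apply(P, 2, stats::sd) / sqrt(n_seeds))
  expect_lt(sum(z[seq_len(length(classes) - 1L)]^2),
            qchisq(0.99, df = length(classes) - 1L))
})

test_that("selection on synonymous mutations skews their spectrum", {
  cfg0 <- tiny_neutral_config()
  singleton_share <- function(cfg, seeds) {
    x <- NULL
    for (s in seeds) {
      lay <- generate_layout(300, 1200, cfg$target_exonic, seed = s)
      st <- simulate_population(cfg, lay, seed = 900 + s)
      sp <- sample_sfs(st, cfg$sample_n, seed = s)
      x <- if (is.null(x)) sp$synonymous else sum_sfs(x, sp$synonymous)
    }
    x$counts[2] / segregating_sites(x)
  }
  # gamma = 2 N s_het = N s_hom = 2 at s = 0.01, N = 200
  cfg_sel <- cfg0
  cfg_sel$syn_model <- selection_model("constant", s = 0.01)
  s_neu <- singleton_share(cfg0, 1:6)
  s_sel <- singleton_share(cfg_sel, 1:6)
  expect_gt(s_sel, s_neu)
  # mean derived sample frequency drops under strong selection
  cfg_str <- cfg0
  cfg_str$syn_model <- selection_model("constant", s = 0.1)  # gamma = 20
  s_str <- singleton_share(cfg_str, 1:6)
  expect_gt(s_str, s_sel)
})

test_that("rescaling leaves per-site diversity invariant", {
  base <- sim_config(N = 2000, mu = 1.5e-7, r = 1e-7, burn_in = 20000,
                     extra_generations = 100, sample_n = 40,
                     ns_model = selection_model("neutral"),
                     syn_model = selection_model("neutral"),
                     mean_exon_len = 300, mean_intron_len = 1200,
                     target_exonic = 3e4, purge_every = 25)
  theta_site <- 4 * base$N * base$mu
  pis <- list()
  for (Q in c(5, 10, 20)) {
    cfg <- rescale(base, Q)
    v <- numeric(6)
    for (s in 1:6) {
      lay <- generate_layout(300, 1200, cfg$target_exonic, seed = s)
      st <- simulate_population(cfg, lay, seed = 70 + s)
      sp <- sample_sfs(st, cfg$sample_n, seed = s)
      v[s] <- sfs_pi(sum_sfs(sp$synonymous, sp$nonsynonymous)) /
        cfg$target_exonic
    }
    pis[[as.character(Q)]] <- v
    expect_lt(abs(mean(v) - theta_site),
              3 * stats::sd(v) / sqrt(6) + 0.05 * theta_site)
  }
  # Q = 5 and Q = 20 agree with each other within sampling error
  expect_lt(abs(mean(pis[["5"]]) - mean(pis[["20"]])),
            3 * sqrt(stats::var(pis[["5"]]) / 6 +
                       stats::var(pis[["20"]]) / 6) + 0.05 * theta_site)
})

test_that("single-locus dynamics match the exact transition matrix", {
  N <- 12
  gens <- 8
  for (s in c(0, 0.3)) {
    exact <- wf_exact_allele_distribution(N, s, n1_0 = 6, n2_0 = 3,
                                          gens = gens)
    reps <- 3000
    sim <- table(factor(vapply(
      seq_len(reps),
      function(k) simulate_single_locus(N, s, 6, 3, gens, seed = 5000 + k),
      0), levels = 0:(2 * N))) / reps
    # twice the Monte-Carlo noise floor separates model error from noise
    expect_lt(tv_dist(as.numeric(sim), as.numeric(exact)),
              2 * expected_tv_noise(as.numeric(exact), reps))
  }
})

test_that("strong selection holds derived frequencies below neutral", {
  # mean sample frequency of a strongly deleterious class falls below the
  # neutral class within the same simulation (gamma ~ 40)
  cfg <- tiny_neutral_config(N = 200)
  cfg$ns_model <- selection_model("constant", s = 0.2)
  lay <- generate_layout(300, 1200, cfg$target_exonic, seed = 11)
  freqs <- c(ns = 0, syn = 0); wt <- c(ns = 0, syn = 0)
  for (s in 1:4) {
    st <- simulate_population(cfg, lay, seed = 1100 + s)
    sp <- sample_sfs(st, 50, seed = s)
    i <- seq_len(49)
    freqs["ns"] <- freqs["ns"] + sum(polymorphic(sp$nonsynonymous) * i)
    wt["ns"] <- wt["ns"] + segregating_sites(sp$nonsynonymous)
    freqs["syn"] <- freqs["syn"] + sum(polymorphic(sp$synonymous) * i)
    wt["syn"] <- wt["syn"] + segregating_sites(sp$synonymous)
  }
  expect_lt(freqs[["ns"]] / wt[["ns"]], freqs[["syn"]] / wt[["syn"]])
})

test_that("sampled allele counts follow the hypergeometric law", {
  cfg <- tiny_neutral_config(N = 60, L_ex = 2e4)
  lay <- generate_layout(300, 1200, 2e4, seed = 5)
  st <- simulate_population(cfg, lay, seed = 8)
  # pick a mid-frequency mutation and resample the haplotypes many times
  k <- st$mutations$count_pop
  target <- which(k >= 40 & k <= 80)[1]
  expect_false(is.na(target))
  K <- k[target]
  n <- 20
  idx <- st$mutations$id[target]
  haps <- st$haplotypes[[1]]
  carriers <- vapply(haps, function(h) idx %in% h, TRUE)
  expect_equal(sum(carriers), K)
  draws <- vapply(1:2000, function(r) {
    picked <- syndfe:::with_seed(10000 + r,
                                 sample.int(length(haps), n))
    sum(carriers[picked])
  }, 0)
  exact <- stats::dhyper(0:n, K, 2 * cfg$N - K, n)
  emp <- as.numeric(table(factor(draws, levels = 0:n))) / length(draws)
  expect_lt(tv_dist(emp, exact), 0.05)
})

test_that("sampling the whole deme returns population counts", {
  cfg <- tiny_neutral_config(N = 40, L_ex = 1e4)
  lay <- generate_layout(300, 1200, 1e4, seed = 6)
  st <- simulate_population(cfg, lay, seed = 9)
  sp <- sample_sfs(st, 2 * cfg$N, seed = 1)
  tot <- sum_sfs(sp$synonymous, sp$nonsynonymous)
  tot$class_label <- "other"
  expect_equal(segregating_sites(tot),
               sum(st$mutations$count_pop > 0 &
                     st$mutations$count_pop < 2 * cfg$N))
  expect_equal(length(sp$synonymous$counts), 2 * cfg$N + 1)
  expect_error(sample_sfs(st, 2 * cfg$N + 1), "exceeds")
})

test_that("class opportunity lengths split the exonic sequence 2.31:1", {
  cfg <- tiny_neutral_config(N = 30, L_ex = 1e4)
  lay <- generate_layout(300, 1200, 1e4, seed = 2)
  st <- simulate_population(cfg, lay, seed = 3)
  sp <- sample_sfs(st, 20, seed = 1)
  expect_equal(sp$nonsynonymous$L / sp$synonymous$L, 2.31)
  expect_equal(sp$nonsynonymous$L + sp$synonymous$L, 1e4)
})

test_that("chunked replicates sum their spectra deterministically", {
  cfg <- tiny_neutral_config(N = 50, L_ex = 1e4)
  one <- simulate_replicate(cfg, n_chunks = 1, seed = 5, sample_n = 20)
  expect_s3_class(one$synonymous, "sfs")
  two <- simulate_replicate(cfg, n_chunks = 2, seed = 5, sample_n = 20)
  expect_equal(two$synonymous$L, 2 * one$synonymous$L)
  again <- simulate_replicate(cfg, n_chunks = 2, seed = 5, sample_n = 20)
  expect_identical(two$synonymous$counts, again$synonymous$counts)
  expect_identical(two$nonsynonymous$counts, again$nonsynonymous$counts)
})

test_that("a split deme with migration yields sampleable spectra", {
  dem <- demography_model(
    demes = list(
      A = data.frame(duration = 600, size = 80),
      B = data.frame(duration = 200, size = 40)),
    splits = data.frame(time = 400, parent = "A", child = "B"),
    migration = list(list(
      from_time = 400,
      rates = matrix(c(0, 1e-3, 1e-3, 0), 2, 2,
                     dimnames = list(c("A", "B"), c("A", "B"))))),
    total_generations = 600)
  cfg <- sim_config(N = 80, mu = 1.5e-6, r = 1e-6, sample_n = 20,
                    syn_model = selection_model("neutral"),
                    mean_exon_len = 300, mean_intron_len = 1200,
                    target_exonic = 2e4, demography = dem,
                    purge_every = 25)
  lay <- generate_layout(300, 1200, 2e4, seed = 4)
  st <- simulate_population(cfg, lay, seed = 12)
  expect_length(st$haplotypes, 2)
  expect_length(st$haplotypes[[2]], 80)
  spB <- sample_sfs(st, 20, seed = 1, deme = 2)
  expect_gt(segregating_sites(spB$synonymous) +
              segregating_sites(spB$nonsynonymous), 0)
  # determinism holds for multi-deme runs too
  st2 <- simulate_population(cfg, lay, seed = 12)
  expect_identical(st$mutations, st2$mutations)
})
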
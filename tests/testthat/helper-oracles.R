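# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# mean pairwise difference (total) computed directly from a site-by-
# haplotype 0/1 matrix
brute_force_pi <- function(mat) {
  n <- ncol(mat)
  tot <- 0
  for (a in seq_len(n - 1)) {
    for (b in seq(a + 1, n)) {
      tot <- tot + sum(mat[, a] != mat[, b])
    }
  }
  tot / choose(n, 2)
}

# high-precision Gauss-Kronrod quadrature of the equilibrium density
# (pracma, independent of stats::integrate and of the diffusion solver)
quadgk_equilibrium_sfs <- function(n, theta, gamma) {
  sel <- function(x) {
    if (gamma == 0) return(1 - x)
    g <- -gamma
    exp(-2 * g * x) * (-expm1(-2 * g * (1 - x))) / (-expm1(-2 * g))
  }
  sapply(seq_len(n - 1), function(i) {
    f <- function(x) {
      v <- exp(lchoose(n, i) + (i - 1) * log(x) +
                 (n - i - 1) * log1p(-x)) * sel(x)
      v[!is.finite(v)] <- 0
      v
    }
    theta * pracma::quadgk(f, 1e-12, 1 - 1e-12, tol = 1e-12)
  })
}

# exact one-generation update of the simulator's reproduction scheme for a
# single biallelic locus: offspring alleles are iid Bernoulli(q) with
# q = sum over parents of fitness-weighted transmitted-derived probability,
# and genotype counts are multinomial. State = (n1, n2) heterozygote /
# derived-homozygote counts among N diploids.
wf_genotype_states <- function(N) {
  st <- expand.grid(n1 = 0:N, n2 = 0:N)
  st[st$n1 + st$n2 <= N, ]
}

wf_transition_matrix <- function(N, s) {
  st <- wf_genotype_states(N)
  S <- nrow(st)
  w1 <- 1 - 0.5 * s
  w2 <- 1 - s
  P <- matrix(0, S, S)
  for (k in seq_len(S)) {
    n1 <- st$n1[k]; n2 <- st$n2[k]; n0 <- N - n1 - n2
    wbar <- n0 + n1 * w1 + n2 * w2
    q <- (0.5 * n1 * w1 + n2 * w2) / wbar
    p0 <- (1 - q)^2; p1 <- 2 * q * (1 - q); p2 <- q^2
    for (j in seq_len(S)) {
      m1 <- st$n1[j]; m2 <- st$n2[j]; m0 <- N - m1 - m2
      P[k, j] <- exp(lfactorial(N) - lfactorial(m0) - lfactorial(m1) -
                       lfactorial(m2) +
                       m0 * log(p0 + 1e-300) + m1 * log(p1 + 1e-300) +
                       m2 * log(p2 + 1e-300))
    }
  }
  list(states = st, P = P)
}

# distribution of the derived ALLELE count after `gens` generations,
# starting from an exact genotype configuration
wf_exact_allele_distribution <- function(N, s, n1_0, n2_0, gens) {
  tm <- wf_transition_matrix(N, s)
  v <- as.numeric(tm$states$n1 == n1_0 & tm$states$n2 == n2_0)
  for (g in seq_len(gens)) v <- as.numeric(v %*% tm$P)
  alleles <- tm$states$n1 + 2 * tm$states$n2
  tapply(v, factor(alleles, levels = 0:(2 * N)), sum, default = 0)
}

# run the simulator itself from a constructed single-locus state and
# return the final derived allele count in the population
simulate_single_locus <- function(N, s, n1_0, n2_0, gens, seed) {
  lay <- generate_layout(mean_exon_len = 10, mean_intron_len = 0,
                         target_exonic = 10)
  cfg <- sim_config(N = N, mu = 0, r = 0, burn_in = 0,
                    extra_generations = 0, sample_n = 2,
                    syn_model = if (s > 0) {
                      selection_model("constant", s = s)
                    } else selection_model("neutral"),
                    ns_model = selection_model("neutral"))
  # genotype layout: first n2_0 individuals homozygous derived, next n1_0
  # heterozygous, rest ancestral
  haps <- lapply(seq_len(2 * N), function(h) {
    ind <- ceiling(h / 2)
    if (ind <= n2_0) 0L
    else if (ind <= n2_0 + n1_0 && h %% 2 == 1) 0L
    else integer(0)
  })
  init <- list(pos = 3, s = s, cls = 0L, haplotypes = list(haps))
  st <- simulate_population(cfg, lay, seed = seed, init_state = init,
                            generations = gens)
  if (nrow(st$mutations) == 0) {
    # lost or fixed (and purged): disambiguate via the substitution log
    if (nrow(st$substitutions) > 0) 2 * N else 0
  } else {
    st$mutations$count_pop[1]
  }
}

# total variation distance between two discrete distributions
tv_dist <- function(p, q) 0.5 * sum(abs(p - q))

# expected total-variation distance between the empirical distribution of
# R draws and the exact distribution, under the exact model (MC noise
# floor): E|phat - p| ~ sqrt(2 p (1-p) / (pi R))
expected_tv_noise <- function(p, R) {
  0.5 * sum(sqrt(2 * p * (1 - p) / (pi * R)))
}
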
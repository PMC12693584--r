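#' Draw fitness effects for new mutations
#'
#' Samples the class (nonsynonymous with probability
#' `ratio / (1 + ratio)`) and selection coefficient of exonic mutations
#' under the configured models — the same distributional rules the forward
#' simulator applies internally. Useful for inspecting a configuration and
#' for distributional checks.
#'
#' @param n_draws Number of mutations to draw.
#' @param config A [sim_config()]; its `N` converts the gamma `2Ns` scale
#'   to homozygous coefficients.
#' @param seed Optional integer seed.
#' @return Tibble with columns `class` ("synonymous"/"nonsynonymous"),
#'   `s` (homozygous magnitude, clamped at 1) and `h` (0.5).
#' @export
draw_mutation_effects <- function(n_draws, config = sim_config(),
                                  seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  N_ref <- reference_N(config)
  with_seed(seed, {
    is_ns <- runif(n_draws) < config$ns_to_s_ratio /
      (1 + config$ns_to_s_ratio)
    s <- numeric(n_draws)
    for (cls in c(TRUE, FALSE)) {
      m <- if (cls) config$ns_model else config$syn_model
      idx <- which(is_ns == cls)
      if (!length(idx)) next
      s[idx] <- switch(m$kind,
        neutral = 0,
        constant = m$s,
        partial = ifelse(runif(length(idx)) < m$p, m$s, 0),
        gamma = pmin(1, rgamma(length(idx), shape = m$shape,
                               scale = m$scale_2Ns / N_ref)))
    }
    tibble::tibble(
      class = ifelse(is_ns, "nonsynonymous", "synonymous"),
      s = s, h = 0.5)
  })
}

# reference diploid size used to convert 2Ns-scaled gamma draws to
# homozygous coefficients: the (root) population size of this config
reference_N <- function(config) {
  if (is.null(config$demography)) return(config$N)
  config$demography$demes[[1L]]$size[1L]
}

model_to_cpp <- function(m, N_ref) {
  kind <- match(m$kind, c("neutral", "constant", "partial", "gamma")) - 1L
  list(kind = kind, s = as.numeric(m$s %||% 0), p = as.numeric(m$p %||% 0),
       shape = as.numeric(m$shape %||% 1),
       scale_s = as.numeric((m$scale_2Ns %||% 0) / N_ref))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# build the per-generation deme size matrix, parent map and migration
# schedule consumed by the C++ engine
demography_schedule <- function(config) {
  if (is.null(config$demography)) {
    gens <- config$burn_in + config$extra_generations
    return(list(
      sizes = matrix(config$N, nrow = gens + 1L, ncol = 1L),
      parent = -1L,
      mig = list(matrix(0, 1, 1)), mig_epoch = rep(0L, gens),
      deme_names = "pop"))
  }
  dem <- config$demography
  gens <- dem$total_generations
  nm <- names(dem$demes)
  D <- length(nm)
  start_gen <- setNames(rep(0L, D), nm)
  if (!is.null(dem$splits)) {
    for (k in seq_len(nrow(dem$splits))) {
      start_gen[dem$splits$child[k]] <- as.integer(dem$splits$time[k])
    }
  }
  sizes <- matrix(0L, nrow = gens + 1L, ncol = D)
  for (d in seq_len(D)) {
    ep <- dem$demes[[d]]
    g0 <- start_gen[nm[d]]
    g <- g0
    for (k in seq_len(nrow(ep))) {
      g1 <- min(gens, g + ep$duration[k])
      if (g1 >= g) sizes[(g + 1L):(g1 + 1L), d] <- as.integer(ep$size[k])
      g <- g1
    }
    if (g < gens) sizes[(g + 1L):(gens + 1L), d] <-
        as.integer(ep$size[nrow(ep)])
    if (g0 > 0L) sizes[seq_len(g0), d] <- 0L
  }
  parent <- rep(-1L, D)
  if (!is.null(dem$splits)) {
    parent[match(dem$splits$child, nm)] <-
      match(dem$splits$parent, nm) - 1L
  }
  if (is.null(dem$migration)) {
    mig <- list(matrix(0, D, D))
    mig_epoch <- rep(0L, gens)
  } else {
    mig <- lapply(dem$migration, `[[`, "rates")
    from <- vapply(dem$migration, `[[`, 0.0, "from_time")
    mig_epoch <- findInterval(seq_len(gens) - 1L, from) - 1L
    if (any(mig_epoch < 0L)) {
      mig <- c(list(matrix(0, D, D)), mig)
      mig_epoch <- mig_epoch + 1L
    }
  }
  list(sizes = sizes, parent = parent, mig = mig, mig_epoch = mig_epoch,
       deme_names = nm)
}

#' Run one forward Wright-Fisher simulation
#'
#' Simulates a diploid population over the configured burn-in and
#' post-burn-in generations on the given genome layout, tracking exonic
#' nonsynonymous and synonymous mutations with multiplicative fitness
#' (heterozygote `1 - s/2`, homozygote `1 - s`), Poisson recombination,
#' and periodic purging of fixed mutations (logged as substitutions).
#'
#' @param config A [sim_config()].
#' @param layout A [generate_layout()] result.
#' @param seed Integer seed (the simulator has its own generator; runs are
#'   reproducible given the seed).
#' @param init_state Optional `population_state` (or its `$raw` part) to
#'   continue from instead of starting mutation-free; used with
#'   `generations` to evolve a constructed state.
#' @param generations Optional override of the number of generations.
#' @return A `population_state`: tibble of segregating `mutations` (with
#'   per-class population counts), the haplotype membership lists, the
#'   substitution log, and the config/layout used.
#' @export
simulate_population <- function(config, layout, seed = 1L,
                                init_state = NULL, generations = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(layout, "genome_layout"))
  sched <- demography_schedule(config)
  if (!is.null(generations)) {
    gens <- as.integer(generations)
    sched$sizes <- sched$sizes[rep(1L, gens + 1L), , drop = FALSE]
    sched$mig_epoch <- rep(if (length(sched$mig_epoch)) {
      sched$mig_epoch[1L]
    } else 0L, gens)
  }
  ex <- layout_exons(layout)
  N_ref <- reference_N(config)
  init <- NULL
  if (!is.null(init_state)) {
    if (inherits(init_state, "population_state")) init_state <- init_state$raw
    init <- init_state
  }
  raw <- .wf_simulate(
    sched$sizes, sched$parent, sched$mig, sched$mig_epoch,
    as.numeric(attr(layout, "total_length")),
    as.numeric(ex$starts), as.numeric(ex$ends),
    config$mu, config$r,
    config$ns_to_s_ratio / (1 + config$ns_to_s_ratio),
    model_to_cpp(config$ns_model, N_ref),
    model_to_cpp(config$syn_model, N_ref),
    2L, 0L,  # a minimal internal sample; real sampling happens in R
    config$purge_every, as.integer(seed), init, TRUE)
  mutations <- tibble::tibble(
    id = seq_along(raw$pos) - 1L, position = raw$pos, s = raw$s,
    class = ifelse(raw$cls == 1L, "nonsynonymous", "synonymous"),
    count_pop = raw$count_pop)
  structure(list(
    mutations = mutations,
    haplotypes = raw$haplotypes,
    substitutions = tibble::as_tibble(raw$substitutions),
    config = config, layout = layout,
    raw = list(pos = raw$pos, s = raw$s, cls = raw$cls,
               haplotypes = raw$haplotypes)),
    class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf(
    "<population_state> %d demes, %s segregating mutations, %s substitutions\n",
    length(x$haplotypes), format(nrow(x$mutations), big.mark = ","),
    format(nrow(x$substitutions), big.mark = ",")))
  invisible(x)
}

#' Sample class-specific spectra from a simulated population
#'
#' Draws `sample_n` haplotypes without replacement from one deme and
#' tallies unfolded synonymous and nonsynonymous spectra. The class
#' sequence lengths are the mutational opportunities
#' `L_ns = exonic * ratio / (1 + ratio)` and `L_s = exonic / (1 + ratio)`.
#'
#' @param state A `population_state`.
#' @param sample_n Haploid sample size.
#' @param seed Optional integer seed for the haplotype draw.
#' @param deme Deme index to sample from.
#' @return List with elements `synonymous` and `nonsynonymous`, both `sfs`.
#' @export
sample_sfs <- function(state, sample_n = 100L, seed = NULL, deme = 1L) {
  stopifnot(inherits(state, "population_state"))
  haps <- state$haplotypes[[deme]]
  if (sample_n > length(haps)) {
    stop("sample_n (", sample_n, ") exceeds the ", length(haps),
         " haplotypes in deme ", deme)
  }
  idx <- with_seed(seed, sample.int(length(haps), sample_n))
  M <- nrow(state$mutations)
  cnt <- integer(M)
  for (h in idx) {
    ids <- haps[[h]]
    cnt[ids + 1L] <- cnt[ids + 1L] + 1L
  }
  ratio <- state$config$ns_to_s_ratio
  exonic <- attr(state$layout, "exonic_length")
  cls <- state$mutations$class
  list(
    synonymous = tally_sfs(cnt[cls == "synonymous"], n = sample_n,
                           L = exonic / (1 + ratio),
                           class_label = "synonymous"),
    nonsynonymous = tally_sfs(cnt[cls == "nonsynonymous"], n = sample_n,
                              L = exonic * ratio / (1 + ratio),
                              class_label = "nonsynonymous"))
}

#' Simulate one replicate as a sum of independent chunks
#'
#' Runs `n_chunks` independent simulations with fresh random genome
#' layouts and child seeds derived from `seed`, samples each, and sums the
#' per-chunk spectra into one replicate synonymous and nonsynonymous
#' spectrum (sequence lengths add). Mirrors the practice of aggregating
#' parallel runs into a replicate representing a large coding
#' complement.
#'
#' @inheritParams simulate_population
#' @param n_chunks Number of independent chunk simulations.
#' @param sample_n Haploid sample size.
#' @param deme Deme to sample (multi-deme configs).
#' @return List with `synonymous` and `nonsynonymous` `sfs`.
#' @export
simulate_replicate <- function(config, n_chunks = 22L, seed = 1L,
                               sample_n = config$sample_n, deme = 1L) {
  stopifnot(inherits(config, "sim_config"), n_chunks >= 1)
  syn <- vector("list", n_chunks)
  ns <- vector("list", n_chunks)
  for (k in seq_len(n_chunks)) {
    lay <- generate_layout(config$mean_exon_len, config$mean_intron_len,
                           config$target_exonic,
                           seed = child_seed(seed, 3L * k))
    st <- simulate_population(config, lay, seed = child_seed(seed, 3L * k + 1L))
    sp <- sample_sfs(st, sample_n, seed = child_seed(seed, 3L * k + 2L),
                     deme = deme)
    syn[[k]] <- sp$synonymous
    ns[[k]] <- sp$nonsynonymous
  }
  list(synonymous = sum_sfs(syn), nonsynonymous = sum_sfs(ns))
}
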
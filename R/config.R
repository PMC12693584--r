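#' Selection model for a mutation class
#'
#' Describes how fitness effects are assigned to new mutations of one
#' class. Selection coefficients are stored as magnitudes of the
#' homozygous effect; dominance is additive (`h = 0.5`, heterozygote
#' fitness `1 - s/2`). Available kinds:
#' \describe{
#'   \item{neutral}{all mutations have `s = 0`.}
#'   \item{constant}{every mutation gets the same `s`.}
#'   \item{partial}{a fraction `p` (default 0.22) gets `s`, the rest 0.}
#'   \item{gamma}{`2 N s` drawn from a gamma distribution with `shape` and
#'     `scale_2Ns` (population-scaled, invariant under rescaling); the
#'     homozygous coefficient is `2Ns / N`.}
#' }
#'
#' @param kind Model kind, see above.
#' @param s Homozygous selection coefficient (constant / partial).
#' @param p Selected fraction (partial).
#' @param shape,scale_2Ns Gamma parameters (gamma kind).
#' @param h Dominance coefficient; only 0.5 is supported by the simulator.
#' @return A `selection_model`.
#' @examples
#' selection_model("gamma", shape = 0.186, scale_2Ns = 706.899)
#' selection_model("partial", s = 1e-4)
#' @export
selection_model <- function(kind = c("neutral", "constant", "partial",
                                     "gamma"),
                            s = 0, p = 0.22, shape = NULL,
                            scale_2Ns = NULL, h = 0.5) {
  kind <- match.arg(kind)
  if (kind %in% c("constant", "partial")) {
    if (!isTRUE(s >= 0)) stop("s must be a non-negative magnitude")
  }
  if (kind == "partial" && !(p >= 0 && p <= 1)) {
    stop("selected fraction p must lie in [0, 1]")
  }
  if (kind == "gamma") {
    if (!isTRUE(shape > 0) || !isTRUE(scale_2Ns > 0)) {
      stop("gamma kind requires positive shape and scale_2Ns")
    }
  }
  if (!identical(h, 0.5)) stop("only additive dominance (h = 0.5) is supported")
  structure(list(kind = kind, s = s, p = p, shape = shape,
                 scale_2Ns = scale_2Ns, h = h),
            class = "selection_model")
}

#' @export
print.selection_model <- function(x, ...) {
  desc <- switch(x$kind,
    neutral = "neutral (s = 0)",
    constant = sprintf("constant s = %g", x$s),
    partial = sprintf("partial: %g%% at s = %g, rest neutral", 100 * x$p,
                      x$s),
    gamma = sprintf("gamma DFE: shape %g, scale (2Ns) %g", x$shape,
                    x$scale_2Ns))
  cat("<selection_model>", desc, "\n")
  invisible(x)
}

#' Simulation configuration
#'
#' Bundles the parameters of one forward simulation run. Defaults are the
#' constant-size human-parameter design: `N` = 10,000 diploids,
#' mutation rate 1.5e-8/bp/generation, recombination 1e-8, a 100,000
#' generation burn-in plus 1,000 further generations before sampling 100
#' haploid genomes, a nonsynonymous:synonymous mutational opportunity
#' ratio of 2.31:1, a gamma nonsynonymous DFE (shape 0.186, 2Ns-scale
#' 706.899, mean homozygous s about 0.013), and neutral synonymous
#' mutations. The genome is an exon/intron mosaic targeting 1.4 Mb exonic
#' in 21 Mb total per run.
#'
#' @param N Diploid population size (ignored when `demography` is given).
#' @param mu Per-bp per-generation mutation rate.
#' @param r Per-bp per-generation recombination rate.
#' @param burn_in,extra_generations Generations before sampling.
#' @param sample_n Haploid sample size.
#' @param ns_to_s_ratio Nonsynonymous:synonymous mutational opportunity.
#' @param ns_model,syn_model [selection_model()]s for the two classes.
#' @param mean_exon_len,mean_intron_len,target_exonic Genome layout
#'   parameters in bp, see [generate_layout()].
#' @param rescale_Q Rescaling factor already applied (see [rescale()]).
#' @param purge_every Generations between fixed-mutation purges.
#' @param demography Optional [demography_model()] overriding constant `N`.
#' @return A `sim_config`.
#' @export
sim_config <- function(N = 10000L, mu = 1.5e-8, r = 1e-8,
                       burn_in = 100000L, extra_generations = 1000L,
                       sample_n = 100L, ns_to_s_ratio = 2.31,
                       ns_model = selection_model("gamma", shape = 0.186,
                                                  scale_2Ns = 706.899),
                       syn_model = selection_model("neutral"),
                       mean_exon_len = 300, mean_intron_len = 4200,
                       target_exonic = 1.4e6, rescale_Q = 1L,
                       purge_every = 500L, demography = NULL) {
  stopifnot(N >= 1, mu >= 0, r >= 0, burn_in >= 0, extra_generations >= 0,
            sample_n >= 2, ns_to_s_ratio > 0, target_exonic > 0)
  structure(list(
    N = as.integer(N), mu = mu, r = r, burn_in = as.integer(burn_in),
    extra_generations = as.integer(extra_generations),
    sample_n = as.integer(sample_n), ns_to_s_ratio = ns_to_s_ratio,
    ns_model = ns_model, syn_model = syn_model,
    mean_exon_len = mean_exon_len, mean_intron_len = mean_intron_len,
    target_exonic = target_exonic, rescale_Q = as.integer(rescale_Q),
    purge_every = as.integer(purge_every), demography = demography),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> N = %s, mu = %g, r = %g, Q = %d\n  burn-in %s + %s gens, sample %d haplotypes\n",
    format(x$N, big.mark = ","), x$mu, x$r, x$rescale_Q,
    format(x$burn_in, big.mark = ","),
    format(x$extra_generations, big.mark = ","), x$sample_n))
  cat("  NS model: "); print(x$ns_model)
  cat("  S model:  "); print(x$syn_model)
  if (!is.null(x$demography)) cat("  multi-deme demography attached\n")
  invisible(x)
}

#' Rescale a configuration for desk-scale simulation
#'
#' Standard population-genetic rescaling by a factor `Q`: `N -> N/Q`,
#' `mu -> Q mu`, `r -> Q r`, selection coefficients `-> Q s`, generation
#' counts `-> /Q`. All population-scaled products (`N mu`, `N r`, `N s`,
#' and hence per-site diversity and SFS shape) are invariant; a gamma DFE
#' specified on the `2Ns` scale needs no adjustment.
#'
#' @param config A `sim_config`.
#' @param Q Integer rescaling factor >= 1.
#' @return The rescaled `sim_config` (with `rescale_Q` multiplied by `Q`).
#' @export
rescale <- function(config, Q) {
  stopifnot(inherits(config, "sim_config"), Q >= 1)
  if (Q == 1) return(config)
  scale_model <- function(m) {
    if (m$kind %in% c("constant", "partial")) {
      if (m$s * Q >= 1) {
        stop("rescaled selection coefficient s*Q = ", m$s * Q,
             " >= 1: fitness would be non-positive")
      }
      m$s <- m$s * Q
    }
    m
  }
  config$ns_model <- scale_model(config$ns_model)
  config$syn_model <- scale_model(config$syn_model)
  config$N <- max(1L, as.integer(round(config$N / Q)))
  config$mu <- config$mu * Q
  config$r <- config$r * Q
  config$burn_in <- as.integer(ceiling(config$burn_in / Q))
  config$extra_generations <- as.integer(ceiling(config$extra_generations / Q))
  config$rescale_Q <- as.integer(config$rescale_Q * Q)
  if (!is.null(config$demography)) {
    config$demography <- rescale_demography(config$demography, Q)
  }
  config
}

#' Multi-deme demographic model for the simulator
#'
#' Piecewise-constant deme sizes with split events and per-epoch
#' migration, sufficient to encode an out-of-Africa-style history.
#' Continuous growth should be discretized into epochs by the caller (the
#' shipped configuration does so).
#'
#' @param demes Named list; each element is a data frame with columns
#'   `duration` (generations, last may be `Inf`-free: durations are counted
#'   forward from the deme's founding) and `size` (diploids).
#' @param splits Data frame with columns `time` (generations from the
#'   start of the whole simulation at which the child is founded),
#'   `parent`, `child` (deme names). Root demes have no split row.
#' @param migration List of epochs, each
#'   `list(from_time =, rates = matrix)` with `rates[dest, src]` the
#'   per-generation fraction of `dest` offspring whose parents come from
#'   `src` (dimnames = deme names). Missing = no migration.
#' @param total_generations Total simulated generations.
#' @return A `demography_model`.
#' @export
demography_model <- function(demes, splits = NULL, migration = NULL,
                             total_generations) {
  stopifnot(is.list(demes), length(demes) >= 1, !is.null(names(demes)))
  for (d in demes) stopifnot(all(d$size >= 1), all(d$duration > 0))
  structure(list(demes = demes, splits = splits, migration = migration,
                 total_generations = as.integer(total_generations)),
            class = "demography_model")
}

rescale_demography <- function(dem, Q) {
  dem$demes <- lapply(dem$demes, function(d) {
    d$duration <- pmax(1, round(d$duration / Q))
    d$size <- pmax(1, round(d$size / Q))
    d
  })
  if (!is.null(dem$splits)) dem$splits$time <- round(dem$splits$time / Q)
  if (!is.null(dem$migration)) {
    dem$migration <- lapply(dem$migration, function(ep) {
      ep$from_time <- round(ep$from_time / Q)
      ep$rates <- ep$rates * Q
      if (any(rowSums(ep$rates) - diag(ep$rates) > 1)) {
        stop("rescaled migration rates exceed 1 per generation")
      }
      ep
    })
  }
  dem$total_generations <- as.integer(ceiling(dem$total_generations / Q))
  dem
}

#' Read a simulation configuration from a YAML file
#'
#' Mirrors the arguments of [sim_config()], [selection_model()] and
#' [demography_model()]. See the shipped example
#' `system.file("extdata", "ooa_gutenkunst_approx.yaml", package =
#' "syndfe")` for the multi-deme layout.
#'
#' @param path YAML file path.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  parse_model <- function(m) {
    if (is.null(m)) return(selection_model("neutral"))
    do.call(selection_model, m)
  }
  dem <- NULL
  if (!is.null(y$demography)) {
    dy <- y$demography
    demes <- lapply(dy$demes, function(d) {
      data.frame(duration = vapply(d$epochs, `[[`, 0.0, "duration"),
                 size = vapply(d$epochs, `[[`, 0.0, "size"))
    })
    names(demes) <- vapply(dy$demes, `[[`, "", "name")
    splits <- if (!is.null(dy$splits)) {
      do.call(rbind, lapply(dy$splits, as.data.frame))
    }
    migration <- if (!is.null(dy$migration)) {
      lapply(dy$migration, function(ep) {
        rates <- matrix(0, length(demes), length(demes),
                        dimnames = list(names(demes), names(demes)))
        for (entry in ep$rates) {
          rates[entry$dest, entry$src] <- entry$rate
        }
        list(from_time = ep$from_time, rates = rates)
      })
    }
    dem <- demography_model(demes, splits, migration,
                            total_generations = dy$total_generations)
  }
  args <- y[setdiff(names(y), c("ns_model", "syn_model", "demography"))]
  args$ns_model <- parse_model(y$ns_model)
  args$syn_model <- parse_model(y$syn_model)
  args$demography <- dem
  do.call(sim_config, args)
}
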
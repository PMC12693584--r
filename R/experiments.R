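#' Define a simulation-and-inference scenario
#'
#' A scenario bundles one synonymous-selection condition with the scale
#' knobs of the experiment (rescaling factor, chunks per replicate, coding
#' sequence per chunk, replicate count). The package-default scale is a
#' desk-scale rendering of the full constant-size design: rescaling
#' `Q = 10` (so 1,000 diploids and a 10,000-generation burn-in), 2 chunks
#' of 1 Mb coding sequence per replicate (2 Mb coding, synonymous theta
#' around 360), and 5 replicates. These sizes were fixed from a power
#' calculation on closed-form spectra: the weakest pervasive selection
#' condition (s = 1e-4) yields an expected log-likelihood advantage near
#' 50 for the two-epoch model, more than ten times the decision
#' threshold of 3.
#'
#' @param name Scenario label.
#' @param syn_model [selection_model()] for synonymous mutations
#'   (unrescaled coefficients).
#' @param r Recombination rate per bp per generation (unrescaled).
#' @param n_replicates Replicates to simulate.
#' @param rescale_Q Rescaling factor applied to the base configuration.
#' @param n_chunks Independent chunk simulations per replicate.
#' @param target_exonic Coding bp per chunk.
#' @param demography `"constant"` or a [demography_model()] (unrescaled).
#' @param base_config Base (unrescaled) [sim_config()] overridden by the
#'   arguments above.
#' @return A `scenario`.
#' @export
scenario <- function(name, syn_model = selection_model("neutral"),
                     r = 1e-8, n_replicates = 5L, rescale_Q = 10L,
                     n_chunks = 2L, target_exonic = 1e6,
                     demography = "constant",
                     base_config = sim_config()) {
  cfg <- base_config
  cfg$syn_model <- syn_model
  cfg$r <- r
  cfg$target_exonic <- target_exonic
  if (!identical(demography, "constant")) cfg$demography <- demography
  structure(list(name = name, n_replicates = as.integer(n_replicates),
                 rescale_Q = as.integer(rescale_Q),
                 n_chunks = as.integer(n_chunks),
                 config = rescale(cfg, rescale_Q)),
            class = "scenario")
}

#' The constant-size scenario grid
#'
#' The seven synonymous-selection conditions of the constant-size design
#' (neutral control; constant s in 1e-5, 1e-4, 1e-3; partial 22% at the
#' same three values) at one recombination rate. The full grid over
#' r in {1e-8, 1e-7, 1e-6} spans 14 selection-by-recombination
#' combinations plus controls.
#'
#' @param r Recombination rate(s); one scenario set per value.
#' @param ... Passed to [scenario()] (scale knobs).
#' @return Named list of `scenario` objects.
#' @export
constant_size_scenarios <- function(r = 1e-8, ...) {
  out <- list()
  for (rr in r) {
    tag <- if (length(r) > 1) paste0("_r", format(rr)) else ""
    defs <- list(
      selection_model("neutral"),
      selection_model("constant", s = 1e-5),
      selection_model("constant", s = 1e-4),
      selection_model("constant", s = 1e-3),
      selection_model("partial", s = 1e-5),
      selection_model("partial", s = 1e-4),
      selection_model("partial", s = 1e-3))
    names(defs) <- paste0(c("control", "constant_1e-5", "constant_1e-4",
                            "constant_1e-3", "partial_1e-5",
                            "partial_1e-4", "partial_1e-3"), tag)
    for (nm in names(defs)) {
      out[[nm]] <- scenario(nm, syn_model = defs[[nm]], r = rr, ...)
    }
  }
  out
}

#' Run the full pipeline for one scenario
#'
#' For each replicate: simulate chunked spectra, fit the one- and
#' two-epoch demographic models to the synonymous spectrum, select by
#' likelihood ratio, condition a gamma-DFE fit on the chosen demography
#' (nonsynonymous theta fixed at the mutational-opportunity multiple of
#' the fitted synonymous theta), discretize, and record diversity
#' summaries. Failures are isolated per replicate and recorded in the
#' `error` column rather than aborting the run.
#'
#' The two-epoch demographic surface is maximized with the exhaustive
#' lattice-scan-plus-polish method (see [fit_demography()]); the DFE
#' stage uses `n_starts` random starts.
#'
#' @param sc A [scenario()].
#' @param seed Master seed; every stage derives its own child seed.
#' @param n_starts Optimizer starts for the DFE fitting stage.
#' @param grid Diffusion grid shared across fits.
#' @param progress Print one line per replicate.
#' @return A tibble with one row per replicate: scalar summaries plus
#'   list-columns `syn_sfs`, `ns_sfs`, `demog` (chosen fit), `dfe`.
#' @export
run_scenario <- function(sc, seed = 1L, n_starts = 25L, grid = sfs_grid(),
                         progress = FALSE) {
  stopifnot(inherits(sc, "scenario"))
  cfg <- sc$config
  rows <- vector("list", sc$n_replicates)
  for (i in seq_len(sc$n_replicates)) {
    rep_seed <- child_seed(seed, 1000L * i)
    rows[[i]] <- tryCatch({
      sp <- simulate_replicate(cfg, n_chunks = sc$n_chunks,
                               seed = rep_seed)
      syn <- sp$synonymous
      ns <- sp$nonsynonymous
      fit1 <- fit_demography(syn, "one_epoch", mu = cfg$mu, L_s = syn$L,
                             grid = grid)
      fit2 <- fit_demography(syn, "two_epoch", mu = cfg$mu, L_s = syn$L,
                             method = "grid", grid = grid)
      chosen <- select_model_lrt(fit1, fit2)
      cache <- build_gamma_cache(chosen)
      dfe <- fit_dfe(ns, cache,
                     theta_ns = cfg$ns_to_s_ratio * chosen$theta,
                     n_starts = n_starts,
                     seed = child_seed(rep_seed, 8L))
      pr_s <- pi_ratio(syn, N = cfg$N, mu = cfg$mu)
      pr_n <- pi_ratio(ns, N = cfg$N, mu = cfg$mu)
      if (progress) {
        message(sprintf("%s rep %d: %s dLL=%.1f shape=%.3f scale=%.0f",
                        sc$name, i, chosen$model, chosen$delta_ll,
                        dfe$shape, dfe$scale_gamma))
      }
      tibble::tibble(
        scenario = sc$name, replicate = i, ns_ratio = cfg$ns_to_s_ratio,
        rescale_Q = cfg$rescale_Q, model = chosen$model,
        nu = chosen$nu, T = chosen$T, delta_ll = chosen$delta_ll,
        theta_s = chosen$theta, N_a = chosen$N_a,
        at_bound = any(chosen$at_bounds), converged = chosen$converged,
        shape = dfe$shape, scale_gamma = dfe$scale_gamma,
        scale_s_dhet = dfe$scale_s_dhet,
        pi_ratio_syn = pr_s$ratio, pi_ratio_ns = pr_n$ratio,
        error = NA_character_,
        syn_sfs = list(syn), ns_sfs = list(ns),
        demog = list(chosen), dfe = list(dfe))
    }, error = function(e) {
      tibble::tibble(
        scenario = sc$name, replicate = i, ns_ratio = cfg$ns_to_s_ratio,
        rescale_Q = cfg$rescale_Q, model = NA_character_,
        nu = NA_real_, T = NA_real_, delta_ll = NA_real_,
        theta_s = NA_real_, N_a = NA_real_, at_bound = NA,
        converged = NA, shape = NA_real_, scale_gamma = NA_real_,
        scale_s_dhet = NA_real_, pi_ratio_syn = NA_real_,
        pi_ratio_ns = NA_real_, error = conditionMessage(e),
        syn_sfs = list(NULL), ns_sfs = list(NULL), demog = list(NULL),
        dfe = list(NULL))
    })
  }
  dplyr::bind_rows(rows)
}

#' Re-fit DFEs conditioning on a truly neutral demography
#'
#' Pairs each replicate of a selected scenario with a replicate of the
#' neutral control (by replicate index, recycled) and re-runs the DFE fit
#' for the selected replicate's nonsynonymous spectrum conditional on the
#' control replicate's fitted demography — emulating access to a set of
#' known neutral variants, unlinked to the nonsynonymous sites. Removing
#' the mis-specified demography in this way restores DFE recovery.
#'
#' @param selected_results,neutral_results Tibbles from [run_scenario()].
#' @param n_starts,seed Optimizer settings for the re-fit.
#' @return `selected_results` with swapped-fit columns `swap_shape`,
#'   `swap_scale_gamma`, `swap_scale_s_dhet` and list-column `swap_dfe`.
#' @export
neutral_swap <- function(selected_results, neutral_results,
                         n_starts = 25L, seed = 1L) {
  ok_neutral <- which(is.na(neutral_results$error))
  if (!length(ok_neutral)) stop("no successful neutral replicates to pair")
  out <- selected_results
  out$swap_shape <- NA_real_
  out$swap_scale_gamma <- NA_real_
  out$swap_scale_s_dhet <- NA_real_
  out$swap_dfe <- vector("list", nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!is.na(out$error[i])) next
    j <- ok_neutral[((i - 1L) %% length(ok_neutral)) + 1L]
    nfit <- neutral_results$demog[[j]]
    ns <- out$ns_sfs[[i]]
    if (ns$n != nfit$observed$n) {
      stop("sample-size mismatch between paired replicates")
    }
    cache <- build_gamma_cache(nfit)
    dfe <- fit_dfe(ns, cache,
                   theta_ns = out$ns_ratio[i] * nfit$theta,
                   n_starts = n_starts, seed = child_seed(seed, i))
    out$swap_shape[i] <- dfe$shape
    out$swap_scale_gamma[i] <- dfe$scale_gamma
    out$swap_scale_s_dhet[i] <- dfe$scale_s_dhet
    out$swap_dfe[[i]] <- dfe
  }
  out
}

#' Write result tables, spectra and figures for a set of runs
#'
#' Writes `results.csv` (scalar columns), per-replicate spectra in fs
#' format under `spectra/`, and the standard figures (inferred size
#' trajectories, DFE shape/scale scatter, discretized-DFE bars, diversity
#' ratios) as PNGs.
#'
#' @param results Tibble from [run_scenario()] (rows of several scenarios
#'   may be bound together).
#' @param out_dir Output directory (created if missing).
#' @param true_shape,true_scale_gamma Generating DFE parameters drawn in
#'   the figures.
#' @return Invisibly, the paths written.
#' @export
report_results <- function(results, out_dir, true_shape = 0.186,
                           true_scale_gamma = 706.899) {
  if (is.null(results) || nrow(results) == 0L) {
    warning("no results to report; nothing written")
    return(invisible(character()))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "spectra"), showWarnings = FALSE)
  scalar <- results[vapply(results, function(c) !is.list(c), TRUE)]
  paths <- file.path(out_dir, "results.csv")
  readr::write_csv(scalar, paths[1L])
  for (i in seq_len(nrow(results))) {
    if (!is.na(results$error[i])) next
    base <- sprintf("%s_rep%02d", results$scenario[i],
                    results$replicate[i])
    for (cls in c("syn", "ns")) {
      p <- file.path(out_dir, "spectra", paste0(base, "_", cls, ".fs"))
      write_fs(results[[paste0(cls, "_sfs")]][[i]], p)
      paths <- c(paths, p)
    }
  }
  figs <- list(
    inferred_size = plot_inferred_size(results),
    shape_scale = plot_shape_scale(results, true_shape, true_scale_gamma),
    dfe_bins = plot_dfe_bins(results, true_shape, true_scale_gamma),
    pi_ratio = plot_pi_ratio(results))
  for (nm in names(figs)) {
    p <- file.path(out_dir, paste0(nm, ".png"))
    ggplot2::ggsave(p, figs[[nm]], width = 7, height = 5, dpi = 150)
    paths <- c(paths, p)
  }
  invisible(paths)
}
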
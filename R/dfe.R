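#' Cache of expected spectra across a grid of selection coefficients
#'
#' DFE inference integrates the expected spectrum over a gamma distribution
#' of population-scaled coefficients \eqn{\gamma = 2 N_a s_{het}}. This
#' pre-computes, under the conditioning demography, one unit-theta expected
#' spectrum per grid point on a log-spaced grid of |gamma| plus the neutral
#' endpoint gamma = 0, so that each likelihood evaluation is a cheap
#' weighted sum.
#'
#' @param fit The conditioning `demog_fit` (typically the model selected by
#'   [select_model_lrt()]).
#' @param gamma_range Range of |gamma| spanned by the grid.
#' @param n_grid Number of positive grid points.
#' @return A `gamma_grid_cache`: gammas (magnitudes, first entry 0), a
#'   spectra matrix (one row per gamma, polymorphic bins only), sample
#'   size, and the conditioning fit.
#' @export
build_gamma_cache <- function(fit, gamma_range = c(1e-4, 2000),
                              n_grid = 81L) {
  stopifnot(inherits(fit, "demog_fit"))
  if (gamma_range[1] > 1e-4 || gamma_range[2] < 2000) {
    stop("gamma grid must span at least [1e-4, 2000]")
  }
  gam <- exp(seq(log(gamma_range[1]), log(gamma_range[2]),
                 length.out = n_grid))
  gam[1L] <- gamma_range[1]
  gam[n_grid] <- gamma_range[2]
  n <- fit$observed$n
  rows <- vector("list", n_grid + 1L)
  ok <- logical(n_grid + 1L)
  for (k in seq_len(n_grid + 1L)) {
    g <- if (k == 1L) 0 else -gam[k - 1L]
    rows[[k]] <- tryCatch(
      polymorphic(expected_sfs(fit, gamma = g, theta = 1)),
      error = function(e) NULL)
    ok[k] <- !is.null(rows[[k]]) && all(is.finite(rows[[k]]))
  }
  if (!ok[1L]) stop("solver failed at the neutral endpoint")
  if (!all(ok)) {
    keep <- which(ok)
    warning("solver failed at ", sum(!ok), " grid gamma values; ",
            "grid truncated")
    gam <- gam[keep[-1L] - 1L]
    rows <- rows[keep]
  }
  spectra <- do.call(rbind, rows)
  structure(list(gammas = c(0, gam), spectra = spectra, n = n, fit = fit),
            class = "gamma_grid_cache")
}

# gamma-distribution weights over the |gamma| grid: probability mass in
# each cell (edges at geometric midpoints); mass below the smallest
# positive grid point goes to the neutral endpoint, mass above the largest
# to the top entry (whose polymorphic contribution is negligible anyway)
gamma_grid_weights <- function(gammas, shape, scale_gamma) {
  g <- gammas[-1L]
  m <- length(g)
  edges <- c(g[1L], sqrt(g[-m] * g[-1L]), Inf)
  c(pgamma(g[1L], shape, scale = scale_gamma),
    diff(pgamma(edges, shape = shape, scale = scale_gamma)))
}

#' Expected nonsynonymous spectrum under a gamma DFE
#'
#' Mixture over the cached grid:
#' \deqn{E[SFS] = \theta_{ns} \int SFS_{unit}(\gamma)\,
#'   f(\gamma; a, b)\, d\gamma}
#' with `f` the gamma density with shape `a = shape` and scale
#' `b = scale_gamma` (in `2 N_a s` units), evaluated by exact binning of
#' the gamma mass onto the log grid.
#'
#' @param cache A `gamma_grid_cache`.
#' @param shape,scale_gamma Gamma DFE parameters (scale in `2 N_a s_het`
#'   units, magnitude of the deleterious coefficient).
#' @param theta_ns Population-scaled nonsynonymous mutation rate.
#' @return An `sfs` of expected counts.
#' @export
expected_sfs_under_dfe <- function(cache, shape, scale_gamma, theta_ns) {
  stopifnot(inherits(cache, "gamma_grid_cache"))
  if (!isTRUE(is.finite(shape) && shape > 0) ||
      !isTRUE(is.finite(scale_gamma) && scale_gamma > 0)) {
    stop("shape and scale_gamma must be positive and finite")
  }
  w <- gamma_grid_weights(cache$gammas, shape, scale_gamma)
  counts <- numeric(cache$n + 1L)
  counts[seq(2L, cache$n)] <-
    theta_ns * as.numeric(crossprod(cache$spectra, w))
  sfs(counts, n = cache$n, class_label = "nonsynonymous")
}

#' Fit a gamma DFE to a nonsynonymous spectrum
#'
#' Maximizes the Poisson composite likelihood over (shape, scale) of a
#' gamma distribution of deleterious population-scaled coefficients,
#' conditional on the demography baked into `cache`. The nonsynonymous
#' mutation rate `theta_ns` is fixed (conventionally 2.31 x the fitted
#' synonymous theta, the nonsynonymous:synonymous mutational opportunity
#' ratio) rather than re-estimated. `n_starts` random starts are refined
#' by box-constrained quasi-Newton optimization in log-parameter space.
#'
#' @inheritParams expected_sfs_under_dfe
#' @param observed Unfolded nonsynonymous `sfs`.
#' @param n_starts Number of optimizer starts.
#' @param seed Optional integer seed for the random starts.
#' @return A `dfe_fit` with `shape`, `scale_gamma`, the heterozygous-unit
#'   scale `scale_s_dhet = scale_gamma / (2 N_a)` (when the conditioning
#'   fit carries an `N_a`), `loglik`, and the per-start table.
#' @export
fit_dfe <- function(observed, cache, theta_ns, n_starts = 25L,
                    seed = NULL) {
  stopifnot(inherits(observed, "sfs"), !observed$folded,
            inherits(cache, "gamma_grid_cache"))
  if (observed$n != cache$n) stop("sample size mismatch with cache")
  if (!isTRUE(theta_ns > 0)) stop("theta_ns must be positive")
  negll <- function(p) {
    m <- expected_sfs_under_dfe(cache, exp(p[1]), exp(p[2]), theta_ns)
    ll <- poisson_loglik(m, observed)
    if (!is.finite(ll)) return(1e12)
    -ll
  }
  lb <- log(c(1e-3, 1e-2))
  ub <- log(c(100, 1e5))
  starts <- with_seed(seed, {
    cbind(runif(n_starts, log(0.05), log(2)),
          runif(n_starts, log(5), log(5000)))
  })
  res <- vector("list", n_starts)
  for (k in seq_len(n_starts)) {
    res[[k]] <- tryCatch({
      o <- optim(starts[k, ], negll, method = "L-BFGS-B", lower = lb,
                 upper = ub, control = list(maxit = 120L, factr = 1e8))
      tibble::tibble(shape = exp(o$par[1]), scale_gamma = exp(o$par[2]),
                     loglik = -o$value, code = o$convergence)
    }, error = function(e) {
      tibble::tibble(shape = NA_real_, scale_gamma = NA_real_,
                     loglik = -Inf, code = -1L)
    })
  }
  starts_tbl <- dplyr::bind_rows(res)
  if (all(!is.finite(starts_tbl$loglik))) {
    stop("all optimizer starts failed; per-start log:\n",
         paste(utils::capture.output(print(starts_tbl)), collapse = "\n"))
  }
  best <- starts_tbl[which.max(starts_tbl$loglik), ]
  N_a <- cache$fit$N_a
  structure(
    list(shape = best$shape, scale_gamma = best$scale_gamma,
         scale_s_dhet = if (is.na(N_a)) NA_real_ else
           scale_to_s(best$scale_gamma, N_a),
         theta_ns = theta_ns, loglik = best$loglik, N_a_used = N_a,
         n_starts = n_starts, starts = starts_tbl, cache_n = cache$n),
    class = "dfe_fit")
}

#' @export
print.dfe_fit <- function(x, ...) {
  cat(sprintf(
    "<dfe_fit> shape = %.4g, scale (2Na s) = %.4g, logLik = %.3f\n",
    x$shape, x$scale_gamma, x$loglik))
  if (!is.na(x$scale_s_dhet)) {
    cat(sprintf("  scale (s_dhet) = %.4g using N_a = %.4g\n",
                x$scale_s_dhet, x$N_a_used))
  }
  invisible(x)
}

#' @export
tidy.dfe_fit <- function(x, ...) {
  tibble::tibble(term = c("shape", "scale_gamma", "scale_s_dhet"),
                 estimate = c(x$shape, x$scale_gamma, x$scale_s_dhet))
}

#' @export
glance.dfe_fit <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, theta_ns = x$theta_ns,
                 N_a_used = x$N_a_used, n_starts = x$n_starts)
}

#' Convert a population-scaled DFE scale to heterozygous-selection units
#'
#' `s_dhet = gamma / (2 N_a)`.
#'
#' @param scale_gamma Scale in `2 N_a s_het` units.
#' @param N_a Ancestral diploid size (> 0).
#' @return Scale in heterozygous selection-coefficient units.
#' @export
scale_to_s <- function(scale_gamma, N_a) {
  if (!isTRUE(N_a > 0)) stop("N_a must be positive")
  scale_gamma / (2 * N_a)
}

#' Discretize a gamma DFE into selection-strength bins
#'
#' Probability mass of the fitted gamma distribution in the conventional
#' bins from neutral (0 to 1e-5) through nearly neutral and moderately
#' deleterious to strongly deleterious (> 0.01), on the selection
#' coefficient scale of `scale_s`. The default uses exact regularized
#' incomplete gamma CDF differences; `method = "mc"` instead draws
#' `n_draws` values (for parity with Monte-Carlo-based reporting).
#'
#' @param shape Gamma shape parameter.
#' @param scale_s Gamma scale in selection-coefficient units.
#' @param edges Increasing bin edges, first 0, last `Inf`.
#' @param method `"cdf"` (exact) or `"mc"` (Monte Carlo).
#' @param n_draws Number of draws for `method = "mc"`.
#' @param seed Optional seed for `method = "mc"`.
#' @return A `dfe_discretized` tibble with columns `bin`, `lower`,
#'   `upper`, `mass`; masses sum to 1.
#' @export
discretize_dfe <- function(shape, scale_s,
                           edges = c(0, 1e-5, 1e-4, 1e-3, 1e-2, Inf),
                           method = c("cdf", "mc"), n_draws = 10000L,
                           seed = NULL) {
  method <- match.arg(method)
  if (is.unsorted(edges, strictly = TRUE)) {
    stop("bin edges must be strictly increasing")
  }
  if (!isTRUE(shape > 0) || !isTRUE(scale_s > 0)) {
    stop("shape and scale_s must be positive")
  }
  nb <- length(edges) - 1L
  mass <- if (method == "cdf") {
    diff(pgamma(edges, shape = shape, scale = scale_s))
  } else {
    draws <- with_seed(seed, rgamma(n_draws, shape = shape,
                                    scale = scale_s))
    tabulate(findInterval(draws, edges), nbins = nb) / n_draws
  }
  out <- tibble::tibble(
    bin = paste0("[", format(edges[-length(edges)], trim = TRUE), ", ",
                 format(edges[-1L], trim = TRUE), ")"),
    lower = edges[-length(edges)], upper = edges[-1L], mass = mass)
  class(out) <- c("dfe_discretized", class(out))
  out
}

#' Standardized residuals of discretized DFE masses
#'
#' \eqn{r_b = (inferred_b - true_b) / \sqrt{true_b}} for each bin.
#'
#' @param inferred,true Numeric vectors of bin masses with the same
#'   binning; `true` must be strictly positive.
#' @return Numeric vector of residuals.
#' @export
standardized_residuals <- function(inferred, true) {
  if (length(inferred) != length(true)) stop("bin count mismatch")
  if (any(true <= 0)) stop("true masses must be strictly positive")
  (inferred - true) / sqrt(true)
}
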
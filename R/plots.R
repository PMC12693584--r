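#' Plot a site-frequency spectrum
#'
#' @param object An `sfs`.
#' @param ... Unused.
#' @return A ggplot of polymorphic bin counts.
#' @export
autoplot.sfs <- function(object, ...) {
  df <- tibble::tibble(i = seq_len(object$n - 1L),
                       sites = polymorphic(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$sites)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "derived-allele count", y = "sites",
                  title = paste0(object$class_label, " SFS (n = ",
                                 object$n, ")")) +
    ggplot2::theme_minimal()
}

#' Inferred population-size trajectories
#'
#' One step function per replicate (time before present in units of
#' `2 N_a` generations): a flat line at the inferred ancestral size for
#' one-epoch fits, a step from `N_a` to `nu * N_a` at the inferred change
#' time for two-epoch fits.
#'
#' @param results Tibble from [run_scenario()].
#' @return A ggplot faceted by scenario.
#' @export
plot_inferred_size <- function(results) {
  ok <- results[is.na(results$error), ]
  t_max <- max(c(ok$T[ok$model == "two_epoch"], 0.1), na.rm = TRUE) * 1.2
  traj <- dplyr::bind_rows(lapply(seq_len(nrow(ok)), function(i) {
    r <- ok[i, ]
    if (identical(r$model, "two_epoch")) {
      tibble::tibble(scenario = r$scenario, replicate = r$replicate,
                     time = c(-t_max, -r$T, -r$T, 0),
                     N = c(r$N_a, r$N_a, r$N_a * r$nu, r$N_a * r$nu))
    } else {
      tibble::tibble(scenario = r$scenario, replicate = r$replicate,
                     time = c(-t_max, 0), N = c(r$N_a, r$N_a))
    }
  }))
  ggplot2::ggplot(traj, ggplot2::aes(x = .data$time, y = .data$N,
                                     group = .data$replicate)) +
    ggplot2::geom_line(alpha = 0.6, colour = "firebrick") +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::labs(x = "time before present (2 N_a generations)",
                  y = "inferred diploid size") +
    ggplot2::theme_minimal()
}

#' DFE shape/scale scatter across replicates
#'
#' @param results Tibble from [run_scenario()].
#' @param true_shape,true_scale_gamma Generating parameters (star marker);
#'   the scale is drawn in `2 N_a s` units.
#' @return A ggplot.
#' @export
plot_shape_scale <- function(results, true_shape = 0.186,
                             true_scale_gamma = 706.899) {
  ok <- results[is.na(results$error), ]
  ggplot2::ggplot(ok, ggplot2::aes(x = .data$scale_gamma, y = .data$shape,
                                   colour = .data$scenario)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::annotate("point", x = true_scale_gamma, y = true_shape,
                      shape = 8, size = 4) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "gamma-DFE scale (2 N_a s)", y = "gamma-DFE shape") +
    ggplot2::theme_minimal()
}

#' Discretized-DFE bar chart with the generating truth
#'
#' Mean bin mass per scenario (error bars: one standard deviation across
#' replicates) next to the discretized generating DFE.
#'
#' @inheritParams plot_shape_scale
#' @param N_a_true Ancestral size used to place the truth on the
#'   heterozygous-selection scale; defaults to the median inferred `N_a`
#'   of the control-most scenario.
#' @return A ggplot.
#' @export
plot_dfe_bins <- function(results, true_shape = 0.186,
                          true_scale_gamma = 706.899, N_a_true = NULL) {
  ok <- results[is.na(results$error) & !is.na(results$scale_s_dhet), ]
  per_rep <- dplyr::bind_rows(lapply(seq_len(nrow(ok)), function(i) {
    d <- discretize_dfe(ok$shape[i], ok$scale_s_dhet[i])
    d$scenario <- ok$scenario[i]
    d$replicate <- ok$replicate[i]
    d
  }))
  summ <- dplyr::summarise(
    dplyr::group_by(per_rep, .data$scenario, .data$bin),
    mean_mass = mean(.data$mass), sd_mass = stats::sd(.data$mass),
    .groups = "drop")
  if (is.null(N_a_true)) N_a_true <- stats::median(ok$N_a, na.rm = TRUE)
  truth <- discretize_dfe(true_shape,
                          scale_to_s(true_scale_gamma, N_a_true))
  truth$scenario <- "true DFE"
  truth$mean_mass <- truth$mass
  truth$sd_mass <- 0
  summ <- dplyr::bind_rows(summ, truth[, c("scenario", "bin", "mean_mass",
                                           "sd_mass")])
  summ$bin <- factor(summ$bin, levels = unique(truth$bin))
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$bin, y = .data$mean_mass,
                                     fill = .data$scenario)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_mass - .data$sd_mass,
                   ymax = .data$mean_mass + .data$sd_mass),
      position = ggplot2::position_dodge(0.9), width = 0.3) +
    ggplot2::labs(x = "selection-strength bin (s)",
                  y = "probability mass") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x =
                     ggplot2::element_text(angle = 30, hjust = 1))
}

#' Diversity-ratio boxplots
#'
#' `pi/pi0` per scenario for the synonymous and nonsynonymous classes;
#' background selection depresses the synonymous ratio below 1 when
#' synonymous mutations are selected.
#'
#' @param results Tibble from [run_scenario()].
#' @return A ggplot.
#' @export
plot_pi_ratio <- function(results) {
  ok <- results[is.na(results$error), ]
  long <- tidyr::pivot_longer(
    ok[, c("scenario", "replicate", "pi_ratio_syn", "pi_ratio_ns")],
    c("pi_ratio_syn", "pi_ratio_ns"),
    names_to = "class", values_to = "ratio")
  long$class <- ifelse(long$class == "pi_ratio_syn", "synonymous",
                       "nonsynonymous")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$scenario, y = .data$ratio,
                                     fill = .data$class)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = NULL, y = expression(pi / pi[0])) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x =
                     ggplot2::element_text(angle = 30, hjust = 1))
}
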
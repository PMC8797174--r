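#' Plot deletion trajectories (mean and 95% CI per condition)
#'
#' Reproduces the standard presentation of the poaching experiments: one
#' panel per network index, deletion proportion on the x axis, mean index
#' value with a t-based 95% confidence ribbon per deletion type, faceted by
#' deletion metric.
#'
#' @param object A `"deletion_results"` tibble from
#'   [run_deletion_experiment()].
#' @param indices Index columns to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.deletion_results <- function(object,
                                      indices = c("clustering", "diameter",
                                                  "efficiency", "modularity"),
                                      ...) {
  long <- object |>
    as_tibble() |>
    tidyr::pivot_longer(all_of(indices), names_to = "index", values_to = "value") |>
    group_by(.data$metric, .data$type, .data$proportion, .data$index) |>
    summarise(
      mean = mean(.data$value, na.rm = TRUE),
      lo = ci95_mean(.data$value)$ci_lo,
      hi = ci95_mean(.data$value)$ci_hi,
      .groups = "drop"
    )
  ggplot2::ggplot(long, ggplot2::aes(.data$proportion, .data$mean,
                                     colour = .data$type, fill = .data$type)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_grid(index ~ metric, scales = "free_y") +
    ggplot2::labs(x = "deletion proportion", y = "index value",
                  colour = "deletion type", fill = "deletion type") +
    ggplot2::theme_minimal()
}

#' Plot effect-size contrasts along the deletion-proportion axis
#'
#' Hedges' g (with its confidence interval) per network index and deletion
#' proportion, with reference lines at the conventional medium (|g| = 0.5)
#' and large (|g| = 0.8) magnitudes.
#'
#' @param object A `"contrast_results"` tibble from [summarize_contrasts()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.contrast_results <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$proportion, .data$g)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = c(-0.8, -0.5, 0.5, 0.8),
                        linetype = "dashed", linewidth = 0.25, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                             size = 0.3) +
    ggplot2::facet_grid(index ~ metric) +
    ggplot2::labs(x = "deletion proportion",
                  y = "Hedges' g (targeted vs random)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot snapshot density against simulation time
#'
#' Shows the saturation of simulated networks: the fraction of dyads with at
#' least one interaction, per snapshot time step, across simulated
#' populations. The per-step gain in density shrinks as the networks
#' approach their plateau.
#'
#' @param snapshots A tibble of snapshots from [simulate_network()], or a
#'   row-bound collection across populations.
#' @return A ggplot object.
#' @export
plot_density_curve <- function(snapshots) {
  med <- snapshots |>
    group_by(.data$t) |>
    summarise(median_density = stats::median(.data$density), .groups = "drop")
  ggplot2::ggplot(snapshots, ggplot2::aes(.data$t, .data$density)) +
    ggplot2::geom_line(ggplot2::aes(group = purrr::map_chr(.data$network, "id")),
                       alpha = 0.25) +
    ggplot2::geom_line(data = med,
                       ggplot2::aes(.data$t, .data$median_density),
                       colour = "red", linewidth = 1, inherit.aes = FALSE) +
    ggplot2::labs(x = "time step", y = "network density") +
    ggplot2::theme_minimal()
}
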
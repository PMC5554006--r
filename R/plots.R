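#' Plot LD decay with LOESS curve, background threshold and extent
#'
#' @param object An `ld_decay` object.
#' @param point_alpha Alpha for the pair scatter.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ld_decay <- function(object, point_alpha = 0.15, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$distance_cM, y = .data$r2)) +
    ggplot2::geom_point(alpha = point_alpha, size = 0.5) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x,
                         span = object$loess_span, se = FALSE,
                         method.args = list(degree = 1), colour = "steelblue") +
    ggplot2::geom_hline(yintercept = object$threshold_r2, linetype = "dashed") +
    { if (!is.na(object$extent_cM))
        ggplot2::geom_vline(xintercept = object$extent_cM, colour = "firebrick") } +
    ggplot2::labs(x = "Genetic distance (cM)", y = expression(r^2),
                  title = sprintf("LD decay (extent %.1f cM)", object$extent_cM)) +
    ggplot2::theme_minimal()
}

#' Plot temporal QTL trajectories
#'
#' One line per QTL: `-log10(p)` over days (or the per-day variance
#' explained when `what = "var_explained"`).
#'
#' @param trajectories A `qtl_trajectories` tibble.
#' @param what `"neg_log10_p"` or `"var_explained"`.
#' @return A ggplot object.
#' @export
plot_qtl_trajectories <- function(trajectories, what = c("neg_log10_p",
                                                         "var_explained")) {
  what <- match.arg(what)
  long <- tidyr::unnest(trajectories, "series")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$day, y = .data[[what]],
                                     colour = .data$marker_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = long[long$significant, ], size = 1.4) +
    ggplot2::labs(x = "Days after sowing",
                  y = if (what == "neg_log10_p") expression(-log[10](p))
                      else "Share of genetic variance",
                  colour = "QTL") +
    ggplot2::theme_minimal()
}

#' Plot broad-sense heritability over days
#'
#' @param h2 Tibble from [heritability_by_day()].
#' @return A ggplot object.
#' @export
plot_heritability <- function(h2) {
  ggplot2::ggplot(h2, ggplot2::aes(x = .data$day, y = .data$H2)) +
    ggplot2::geom_col(fill = "grey60") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Days after sowing", y = expression(H^2)) +
    ggplot2::theme_minimal()
}

#' Heatmap of the day-by-day Kendall correlation matrix
#'
#' @param tau Matrix from [kendall_correlation_matrix()].
#' @return A ggplot object.
#' @export
plot_kendall_heatmap <- function(tau) {
  df <- tibble::as_tibble(as.table(tau), .name_repair = "minimal")
  names(df) <- c("day_i", "day_j", "tau")
  df$day_i <- as.numeric(df$day_i); df$day_j <- as.numeric(df$day_j)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day_i, y = .data$day_j,
                                   fill = .data$tau)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(-1, 1)) +
    ggplot2::labs(x = "Day", y = "Day", fill = expression(tau)) +
    ggplot2::theme_minimal()
}

#' Plot standardized biomass trajectories of allele-stacking groups
#'
#' Per-genotype standardized biomass over days, coloured by stacking
#' group, with group means overlaid, faceted by QTL subset.
#'
#' @param object A `stacking_groups` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stacking_groups <- function(object, ...) {
  cols <- c(all_favorable = "forestgreen", all_unfavorable = "firebrick",
            other = "grey70")
  ggplot2::ggplot(object$trajectories,
                  ggplot2::aes(x = .data$day, y = .data$std_biomass,
                               group = .data$genotype, colour = .data$group)) +
    ggplot2::geom_line(alpha = 0.35, linewidth = 0.3) +
    ggplot2::geom_line(data = object$group_means,
                       ggplot2::aes(y = .data$mean_std_biomass,
                                    group = .data$group),
                       linewidth = 1) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::scale_colour_manual(values = cols) +
    ggplot2::facet_wrap(~subset) +
    ggplot2::labs(x = "Days after sowing",
                  y = "Standardized biomass (relative to day mean)",
                  colour = "Allele group") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
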
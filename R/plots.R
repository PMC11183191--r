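# ggplot2 helpers for the main result types. All take tidy tables and
# return ggplot objects the caller can restyle.

#' Scatter of a per-sample quantity against the N dose with an OLS line
#'
#' @param data data frame with the value and `n_rate` columns.
#' @param value name of the column to plot.
#' @param n_rate name of the N rate column.
#' @return a ggplot.
#' @export
plot_gradient <- function(data, value, n_rate = "n_rate") {
  d <- tibble(n_dose = n_dose(data[[n_rate]]), y = data[[value]])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n_dose, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         linewidth = 0.6) +
    ggplot2::labs(x = expression(log[2](N + 1)), y = value) +
    ggplot2::theme_minimal()
}

#' Faceted trends of the seven topology parameters along the gradient
#'
#' @param topology_tbl per-network [topology()] rows with a
#'   `network_id` column holding the N rate.
#' @return a ggplot.
#' @export
plot_topology_trends <- function(topology_tbl) {
  long <- tidyr::pivot_longer(
    dplyr::mutate(topology_tbl,
                  n_dose = n_dose(as.numeric(.data$network_id))),
    dplyr::all_of(topology_metrics),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n_dose, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.6) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = expression(log[2](N + 1)), y = NULL) +
    ggplot2::theme_minimal()
}

#' Cohesion components along the gradient
#'
#' @param cohesion_tbl per-sample [cohesion()] rows.
#' @param metadata per-sample metadata with `n_rate`.
#' @return a ggplot faceted over positive, |negative|, total cohesion
#'   and the negative:positive ratio.
#' @export
plot_cohesion_trends <- function(cohesion_tbl, metadata) {
  d <- dplyr::left_join(cohesion_tbl,
                        metadata[c("sample_id", "n_rate")],
                        by = "sample_id")
  d <- dplyr::transmute(d, n_dose = n_dose(.data$n_rate),
                        positive = .data$pos,
                        `|negative|` = abs(.data$neg),
                        total = .data$total,
                        `neg:pos ratio` = .data$neg_pos_ratio)
  long <- tidyr::pivot_longer(d, -"n_dose", names_to = "component",
                              values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n_dose, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         linewidth = 0.6) +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = expression(log[2](N + 1)), y = "cohesion") +
    ggplot2::theme_minimal()
}

#' Life-history trait indices along the gradient
#'
#' @param indices a [rk_strategy_pc1()] (or [trait_indices()]) table.
#' @param metadata per-sample metadata with `n_rate`.
#' @return a ggplot.
#' @export
plot_trait_trends <- function(indices, metadata) {
  d <- dplyr::left_join(indices, metadata[c("sample_id", "n_rate")],
                        by = "sample_id")
  keep <- intersect(c("copio_oligo_ratio", "cwm_rrn", "cwm_gc", "rk_pc1"),
                    names(d))
  long <- tidyr::pivot_longer(
    dplyr::mutate(d, n_dose = n_dose(.data$n_rate)),
    dplyr::all_of(keep), names_to = "index", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n_dose, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         linewidth = 0.6) +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = expression(log[2](N + 1)), y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn complexity_pc1 scores against network id.
#' @param object a `complexity_pca`.
#' @method autoplot complexity_pca
#' @export
autoplot.complexity_pca <- function(object, ...) {
  d <- object$scores
  d$network_id <- factor(d$network_id, levels = unique(d$network_id))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$network_id, y = .data$pc1)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "network", y = "complexity PC1") +
    ggplot2::theme_minimal()
}

#' @describeIn fit_piecewise_sem dot-whisker plot of standardized paths.
#' @param object a `psem_fit`.
#' @method autoplot psem_fit
#' @export
autoplot.psem_fit <- function(object, ...) {
  d <- object$paths
  d$label <- paste(d$parent, "→", d$child)
  d$significant <- d$p_value < 0.05
  ggplot2::ggplot(d, ggplot2::aes(x = .data$std_estimate,
                                  y = stats::reorder(.data$label,
                                                     .data$std_estimate),
                                  colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "standardized path coefficient", y = NULL,
                  colour = "p < 0.05") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
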
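#' Volcano plot of a hurdle differential-expression table
#'
#' @param object A [run_hurdle_de()] table.
#' @param alpha,min_lnfc Highlighting thresholds (defaults match the DEG
#'   rules for binary variables).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.de_result <- function(object, alpha = 0.05, min_lnfc = 0.1, ...) {
  d <- dplyr::filter(tibble::as_tibble(object), .data$tested)
  d$deg <- d$q < alpha & abs(d$lnfc) > min_lnfc
  ggplot2::ggplot(d, ggplot2::aes(.data$lnfc, -log10(pmax(.data$p, 1e-300)),
                                  colour = .data$deg)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-min_lnfc, min_lnfc),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "ln fold change (model-based)",
                  y = expression(-log[10](p)),
                  title = "Hurdle-model differential expression") +
    ggplot2::theme_minimal()
}

#' Heatmap of pairwise cluster ambiguity
#'
#' @param object An [ambiguity_matrix()] table.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ambiguity_result <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d2 <- dplyr::bind_rows(
    d, dplyr::rename(d, cluster_a = "cluster_b", cluster_b = "cluster_a"))
  ggplot2::ggplot(d2, ggplot2::aes(.data$cluster_a, .data$cluster_b,
                                   fill = .data$percent_intermediate)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.1f", .data$percent_intermediate)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 100),
                                 name = "% intermediate") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Cluster ambiguity (percent intermediate)") +
    ggplot2::theme_minimal()
}

#' Plot normalized ddCT treatment values by duration
#'
#' @param values A [ddct_treatment_normalization()] table.
#' @return A ggplot.
#' @export
plot_ddct_treatment <- function(values) {
  ggplot2::ggplot(values,
                  ggplot2::aes(factor(.data$duration), .data$value,
                               colour = .data$condition)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::geom_jitter(width = 0.15, height = 0, size = 1.5) +
    ggplot2::labs(x = "treatment duration (h)",
                  y = "normalized expression (fold of baseline)") +
    ggplot2::theme_minimal()
}

#' Dot plot of prioritized ligand-to-target edges
#'
#' @param edges A [prioritize_edges()] table.
#' @return A ggplot.
#' @export
plot_ligand_targets <- function(edges) {
  ggplot2::ggplot(edges,
                  ggplot2::aes(.data$target, .data$ligand,
                               size = .data$regulation_strength,
                               colour = .data$target_direction)) +
    ggplot2::geom_point() +
    ggplot2::facet_grid(source_cluster ~ target_cluster, scales = "free",
                        space = "free") +
    ggplot2::labs(x = "target gene", y = "ligand",
                  size = "regulation strength", colour = "target in AD") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
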
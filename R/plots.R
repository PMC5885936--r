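#' Plot a partial correlation matrix as a heatmap
#'
#' @param object A `thicknet_pcm`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.thicknet_pcm <- function(object, ...) {
  df <- tidyr::expand_grid(region_i = object$regions, region_j = object$regions)
  df$partial_r <- as.vector(t(object$values))
  df$region_i <- factor(df$region_i, levels = object$regions)
  df$region_j <- factor(df$region_j, levels = rev(object$regions))
  ggplot2::ggplot(df, ggplot2::aes(.data$region_i, .data$region_j,
                                   fill = .data$partial_r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), name = "partial r") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste0("Partial correlations (n = ", object$n_subjects,
                                 ", k = ", object$k_covariates, ")")) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Plot a binary network with nodes sized by degree
#'
#' @param object A `thicknet_network`.
#' @param layout_seed Seed for the force-directed layout (default 1).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.thicknet_network <- function(object, layout_seed = 1L, ...) {
  g <- .net_to_igraph(object)
  set.seed(layout_seed)
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble::tibble(node = object$regions, x = xy[, 1L], y = xy[, 2L],
                          degree = as.numeric(degree_centrality(object)))
  ed <- network_edges(object)
  ed$x <- nodes$x[match(ed$region_i, nodes$node)]
  ed$y <- nodes$y[match(ed$region_i, nodes$node)]
  ed$xend <- nodes$x[match(ed$region_j, nodes$node)]
  ed$yend <- nodes$y[match(ed$region_j, nodes$node)]
  ggplot2::ggplot(nodes, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(xend = .data$xend, yend = .data$yend),
                          linewidth = 0.2, colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(size = .data$degree), colour = "steelblue") +
    ggplot2::scale_size_continuous(range = c(0.5, 4)) +
    ggplot2::labs(title = paste0(object$edge_count, " edges, wiring cost ",
                                 format(round(object$wiring_cost, 4), nsmall = 4))) +
    ggplot2::theme_void()
}

#' Plot a centrality profile, one panel per measure
#'
#' @param object A `thicknet_centrality` tibble from [centrality_profile()].
#' @param top_n Label the `top_n` highest-ranked nodes per measure (default
#'   10).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.thicknet_centrality <- function(object, top_n = 10L, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"node",
                              names_to = "measure", values_to = "value")
  long$measure <- factor(long$measure, levels = .MEASURES)
  top <- long |>
    dplyr::group_by(.data$measure) |>
    dplyr::slice_max(.data$value, n = top_n, with_ties = FALSE) |>
    dplyr::ungroup()
  ggplot2::ggplot(top, ggplot2::aes(.data$value,
                                    stats::reorder(.data$node, .data$value))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~measure, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL, title = "Top nodes per centrality measure") +
    ggplot2::theme_minimal(base_size = 9)
}

#' Plot a pipeline report: permutation p-values per pair and measure
#'
#' Nodes passing the multi-measure rule are highlighted.
#'
#' @param object A `thicknet_report`.
#' @param alpha Reference per-measure level drawn as a line (default the
#'   report's `perm_alpha`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.thicknet_report <- function(object, alpha = object$config$perm_alpha, ...) {
  df <- tidy(object)
  df$measure <- factor(df$measure, levels = .MEASURES)
  ggplot2::ggplot(df, ggplot2::aes(.data$node, -log10(.data$p_value),
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2, colour = "grey40") +
    ggplot2::facet_grid(measure ~ pair) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                                 name = "3-of-4 rule") +
    ggplot2::labs(x = NULL, y = expression(-log[10](p))) +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
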
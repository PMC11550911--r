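# ggplot2 presentation of the main result objects.

#' @export
autoplot.pst_trace <- function(object, ...) {
  df <- object$trace
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$phi, y = .data$pst)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_lower, ymax = .data$ci_upper),
      fill = "tan", alpha = 0.4
    ) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::labs(
      x = expression(c / h^2), y = expression(P[ST]),
      title = object$trait
    ) +
    ggplot2::theme_minimal()
  if (!is.na(object$fst_global)) {
    p <- p + ggplot2::geom_hline(yintercept = object$fst_global,
                                 linetype = "dotted")
  }
  p
}

#' @export
autoplot.relative_warps <- function(object, axes = c(1, 2), colour = "population",
                                    ...) {
  df <- tidy(object)
  ax <- sprintf("RW%d", axes)
  lab <- sprintf("%s (%.1f%%)", ax, object$pct_variance[axes])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[ax[1]]], y = .data[[ax[2]]]))
  if (colour %in% names(df)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]))
  } else {
    p <- p + ggplot2::geom_point()
  }
  p + ggplot2::labs(x = lab[1], y = lab[2]) + ggplot2::theme_minimal()
}

#' @export
autoplot.dapc_clusters <- function(object, ...) {
  ggplot2::ggplot(object$bic, ggplot2::aes(x = .data$k, y = .data$bic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$best_k, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "number of clusters k", y = "BIC") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fst_result <- function(object, ...) {
  if (is.null(object$pairwise)) {
    abort("no pairwise matrix: run wc_fst(..., pairwise = TRUE)")
  }
  df <- as_tibble(object$pairwise, rownames = "pop1") %>%
    tidyr::pivot_longer(-"pop1", names_to = "pop2", values_to = "fst")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pop1, y = .data$pop2,
                                   fill = .data$fst)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = expression(F[ST])) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
autoplot.tps_grid <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(x = .data$x_def, y = .data$y_def)) +
    ggplot2::geom_point(size = 0.3, colour = "grey40") +
    ggplot2::geom_point(
      data = tibble(x = object$mapped_landmarks[, 1],
                    y = object$mapped_landmarks[, 2]),
      ggplot2::aes(x = .data$x, y = .data$y), colour = "black", size = 1.5
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' @export
autoplot.haplotype_network <- function(object, ...) {
  g <- igraph::graph_from_data_frame(object$edges, directed = FALSE)
  lay <- with_local_seed(1L, igraph::layout_with_fr(g))
  nodes <- tibble(name = igraph::V(g)$name, x = lay[, 1], y = lay[, 2])
  edges <- object$edges %>%
    left_join(nodes, by = c(from = "name")) %>%
    rename(x0 = "x", y0 = "y") %>%
    left_join(nodes, by = c(to = "name"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x,
                   yend = .data$y)
    ) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y),
                        size = 4, colour = "steelblue") +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$name),
      vjust = -1.2, size = 3
    ) +
    ggplot2::theme_void()
}
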
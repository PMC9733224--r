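#' Plot a signed network
#'
#' Draws the stratum network with a deterministic Fruchterman-Reingold
#' layout (seeded), positive edges solid and negative edges dashed;
#' isolated nodes are shown faded to reflect that they pass the abundance
#' filter without joining any association.
#'
#' @param object a [signed_network()].
#' @param label_nodes draw node labels (default FALSE).
#' @param seed layout seed (default 1).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot signed_network
#' @export
autoplot.signed_network <- function(object, label_nodes = FALSE, seed = 1L,
                                    ...) {
  g <- as_igraph(object)
  xy <- withr::with_seed(as.integer(seed), {
    igraph::layout_with_fr(g)
  })
  nodes <- tibble(node = object$nodes, x = xy[, 1L], y = xy[, 2L],
                  connected = object$nodes %in% connected_nodes(object))
  edges <- dplyr::left_join(
    dplyr::left_join(object$edges,
                     dplyr::rename(nodes[1:3], node_u = "node",
                                   x_u = "x", y_u = "y"),
                     by = "node_u"),
    dplyr::rename(nodes[1:3], node_v = "node", x_v = "x", y_v = "y"),
    by = "node_v")
  p <- ggplot2::ggplot()
  if (nrow(edges)) {
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x_u, y = .data$y_u, xend = .data$x_v,
                   yend = .data$y_v,
                   linetype = factor(.data$sign, c(1, -1),
                                     c("positive", "negative")),
                   linewidth = abs(.data$weight)),
      colour = "grey30")
  }
  p <- p +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(.data$x, .data$y,
                                     alpha = .data$connected),
                        size = 2, colour = "#2166AC") +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.25),
                                guide = "none") +
    ggplot2::scale_linewidth(range = c(0.3, 1.2), guide = "none") +
    ggplot2::labs(
      title = sprintf("%s, day %s", object$condition, object$time_point),
      linetype = "association") +
    ggplot2::theme_void()
  if (label_nodes) {
    p <- p + ggplot2::geom_text(data = nodes,
                                ggplot2::aes(.data$x, .data$y,
                                             label = .data$node),
                                size = 2.5, vjust = -1)
  }
  p
}

#' Plot node persistence as a presence heat map
#'
#' Tiles node presence across the time grid, split by classification, so
#' stable cores and one-off transients are visible at a glance.
#'
#' @param object a [persistence_report()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot persistence_report
#' @export
autoplot.persistence_report <- function(object, ...) {
  if (!nrow(object$nodes)) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = sprintf("%s: no nodes observed",
                                           object$condition)))
  }
  long <- separate_rows_compat(object)
  ggplot2::ggplot(long, ggplot2::aes(
    x = factor(.data$time_point, levels = object$time_points),
    y = .data$node, fill = .data$present)) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.2) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166AC",
                                          `FALSE` = "grey90"),
                               guide = "none") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$classification),
                        scales = "free_y", space = "free_y") +
    ggplot2::labs(x = "day post-weaning", y = NULL,
                  title = sprintf("node persistence, %s",
                                  object$condition)) +
    ggplot2::theme_minimal(base_size = 9)
}

# unpack presence_pattern strings into long (node, time_point, present)
separate_rows_compat <- function(report) {
  purrr::map_dfr(seq_len(nrow(report$nodes)), function(i) {
    bits <- strsplit(report$nodes$presence_pattern[i], "")[[1L]]
    tibble(node = report$nodes$node[i],
           classification = report$nodes$classification[i],
           time_point = report$time_points,
           present = bits == "1")
  })
}

#' Plot the StARS instability path
#'
#' Instability D(lambda) and its monotonized envelope against the penalty,
#' with the threshold beta and the selected penalty marked.
#'
#' @param object a [stars_select()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot stars_result
#' @export
autoplot.stars_result <- function(object, ...) {
  d <- tibble(lambda = object$lambda_path,
              instability = object$instability,
              monotone = object$monotone_instability)
  ggplot2::ggplot(d, ggplot2::aes(.data$lambda)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$instability),
                       colour = "grey60") +
    ggplot2::geom_line(ggplot2::aes(y = .data$monotone),
                       colour = "#B2182B") +
    ggplot2::geom_hline(yintercept = object$beta, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$lambda_star,
                        linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(lambda), y = "instability D",
                  title = sprintf("StARS path (lambda* = %.3g)",
                                  object$lambda_star)) +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
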
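#' Plot a voxel image
#'
#' ggplot2 rendering of a back-projected image: one tile per voxel at its
#' grid position, row increasing downward as in the rendered sections.
#' Continuous images use the inferno scale from zero to the section maximum;
#' categorical images use the Okabe-Ito palette.
#'
#' @param object A `voxel_image` from [project_gene()] or
#'   [project_clusters()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.voxel_image <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(object$values, .name_repair = ~as.character(seq_along(.x))),
                  .row = seq_len(nrow(object$values))),
    -".row", names_to = ".col", values_to = "value"
  )
  df$.col <- as.integer(df$.col)
  df <- df[!is.na(df$value), , drop = FALSE]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$.col, y = .data$.row)) +
    ggplot2::coord_equal() +
    ggplot2::scale_y_reverse() +
    ggplot2::theme_void() +
    ggplot2::labs(title = paste0(object$label, " — section ", object$section_id))
  if (object$kind == "continuous") {
    p + ggplot2::geom_tile(ggplot2::aes(fill = .data$value)) +
      ggplot2::scale_fill_gradientn(
        colours = grDevices::hcl.colors(256, "Inferno"),
        limits = c(0, max(df$value)), name = "per million"
      )
  } else {
    p + ggplot2::geom_tile(ggplot2::aes(fill = factor(.data$value))) +
      ggplot2::scale_fill_manual(
        values = unname(grDevices::palette.colors(9, "Okabe-Ito")),
        name = "cluster"
      )
  }
}

#' Plot the nerve graph of a mapper fit
#'
#' Draws the Mapper graph with a deterministic force-directed layout, nodes
#' sized by member count and coloured by segment.
#'
#' @param object A `mapper_fit` from [run_mapper()].
#' @param layout_seed Seed for the graph layout; default 1.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mapper_fit <- function(object, layout_seed = 1, ...) {
  g <- .as_igraph(object$graph)
  xy <- withr::with_seed(layout_seed, igraph::layout_with_fr(g))
  nodes <- object$graph$nodes
  nd <- tibble::tibble(
    x = xy[, 1], y = xy[, 2],
    size = nodes$size,
    community = factor(attr(object$labels, "node_communities"))
  )
  ed <- object$graph$edges
  seg <- tibble::tibble(
    x = nd$x[ed$from], y = nd$y[ed$from],
    xend = nd$x[ed$to], yend = nd$y[ed$to],
    weight = ed$weight
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$weight),
      colour = "grey60"
    ) +
    ggplot2::geom_point(
      data = nd,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$size,
                   colour = .data$community)
    ) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5), guide = "none") +
    ggplot2::scale_size(range = c(1, 6), name = "voxels") +
    ggplot2::scale_colour_manual(
      values = unname(grDevices::palette.colors(9, "Okabe-Ito")),
      name = "segment"
    ) +
    ggplot2::theme_void()
}

#' Marker score overview
#'
#' Plots each cluster's top marker genes by KS score, coloured by direction.
#'
#' @param table A `marker_table` from [cluster_markers()].
#' @param top_n Markers shown per cluster; default 10.
#' @return A ggplot object.
#' @export
plot_markers <- function(table, top_n = 10) {
  df <- dplyr::slice_head(
    dplyr::group_by(dplyr::filter(tidy(table), .data$significant),
                    .data$cluster),
    n = top_n
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$ks_score,
    y = stats::reorder(.data$gene, .data$ks_score),
    fill = .data$direction
  )) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~cluster, scales = "free_y") +
    ggplot2::labs(x = "KS score", y = NULL) +
    ggplot2::theme_minimal()
}
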
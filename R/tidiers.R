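#' Tidy a mapper fit
#'
#' Returns the per-voxel result of the clustering: one row per voxel with
#' its cluster label and lens coordinates.
#'
#' @param x A `mapper_fit` from [run_mapper()].
#' @param ... Unused.
#' @return A tibble `voxel_id`, `cluster`, `lens_1`, `lens_2`, ...
#' @export
tidy.mapper_fit <- function(x, ...) {
  dplyr::left_join(x$labels, x$lens, by = "voxel_id")
}

#' One-row summary of a mapper fit
#'
#' @param x A `mapper_fit`.
#' @param ... Unused.
#' @return A tibble with `n_voxels`, `n_nodes`, `n_edges`, `n_clusters` and
#'   the modularity of the node communities on the weighted nerve.
#' @export
glance.mapper_fit <- function(x, ...) {
  g <- .as_igraph(x$graph)
  comm <- attr(x$labels, "node_communities")
  mod <- if (igraph::ecount(g) > 0L) {
    igraph::modularity(g, comm, weights = igraph::E(g)$weight)
  } else {
    NA_real_
  }
  tibble::tibble(
    n_voxels = nrow(x$labels),
    n_nodes = nrow(x$graph$nodes),
    n_edges = nrow(x$graph$edges),
    n_clusters = length(unique(x$labels$cluster)),
    modularity = mod
  )
}

#' Tidy a marker table
#'
#' A `marker_table` is already tibble-shaped; this strips the subclass and
#' returns the plain tibble.
#'
#' @param x A `marker_table` from [cluster_markers()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.marker_table <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "marker_table")
  tibble::as_tibble(out)
}

#' One-row summary of a marker table
#'
#' @param x A `marker_table`.
#' @param ... Unused.
#' @return A tibble with the number of clusters, genes, the Bonferroni
#'   family size, the significance level and the significant-call count.
#' @export
glance.marker_table <- function(x, ...) {
  tibble::tibble(
    n_clusters = length(unique(x$cluster)),
    n_genes = length(unique(x$gene)),
    m_family = attr(x, "m_family"),
    alpha = attr(x, "alpha"),
    n_significant = sum(x$significant)
  )
}
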
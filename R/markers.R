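#' Two-sample Kolmogorov-Smirnov statistic
#'
#' `D = sup_t |F_x(t) - F_y(t)|` over the two empirical CDFs, evaluated at
#' every pooled unique value so ties are handled exactly. `D` lies in
#' `[0, 1]`.
#'
#' @param x,y Numeric vectors, each of length >= 1, no missing values.
#' @return The KS statistic, a single number in `[0, 1]`.
#' @export
ks_statistic <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) stop("missing values in input", call. = FALSE)
  .ks_stat(x, y)
}

# core statistic without argument checks; used in tight loops
.ks_stat <- function(x, y) {
  n <- length(x)
  m <- length(y)
  w <- c(x, y)
  ord <- order(w)
  steps <- cumsum(ifelse(ord <= n, 1 / n, -1 / m))
  ws <- w[ord]
  at_value <- c(ws[-1L] != ws[-length(ws)], TRUE)  # last index of each tie group
  max(abs(steps[at_value]))
}

#' Kolmogorov-Smirnov p-value
#'
#' Two-sided p-value for the two-sample KS statistic. Small samples
#' (`n * m <= 10000`, the standard cutoff) use the exact conditional
#' distribution ([stats::psmirnov()]), whose far tail the asymptotic
#' approximation understates; larger samples use the asymptotic Kolmogorov
#' distribution evaluated at `sqrt(nm / (n + m)) * D`.
#'
#' @param D KS statistic in `[0, 1]`.
#' @param n,m Sample sizes (>= 1).
#' @return A p-value in `(0, 1]`.
#' @export
ks_pvalue <- function(D, n, m) {
  if (any(D < 0 | D > 1)) stop("D must lie in [0, 1]", call. = FALSE)
  if (n < 1 || m < 1) stop("sample sizes must be >= 1", call. = FALSE)
  if (n * m <= 10000) {
    # psmirnov(lower.tail = FALSE) is P(D >= q), the exact p-value
    vapply(D, function(d) {
      stats::psmirnov(d, sizes = c(n, m), two.sided = TRUE,
                      lower.tail = FALSE, exact = TRUE)
    }, numeric(1))
  } else {
    .kolmogorov_sf(sqrt(n * m / (n + m)) * D)
  }
}

# survival function of the Kolmogorov distribution, vectorised
.kolmogorov_sf <- function(t) {
  vapply(t, function(ti) {
    if (ti <= 0) return(1)
    j <- seq_len(100)
    p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * ti^2))
    min(max(p, 0), 1)
  }, numeric(1))
}

#' Per-cluster marker genes by KS testing
#'
#' For every (cluster, gene) pair, compares the gene's normalized expression
#' in the cluster's voxels against the pooled voxels of all other clusters
#' with a two-sample KS test, Bonferroni-corrects over the whole screen
#' (family size = genes x clusters, so that a significant call controls the
#' family-wise error of the entire marker search at `alpha`), and calls
#' direction from the median difference.
#'
#' @param expr Numeric expression matrix, genes x voxels (per-million
#'   values).
#' @param labels Tibble with columns `voxel_id` and `cluster` covering the
#'   columns of `expr`.
#' @param alpha Family-wise significance level; default 0.05.
#' @param family Bonferroni family: `"global"` (default, m = genes x
#'   clusters) or `"per_cluster"` (m = genes within one cluster-vs-rest
#'   comparison; note the union bound then only guarantees
#'   `alpha * n_clusters` over the whole screen).
#' @return A `marker_table` tibble with columns `cluster`, `gene`,
#'   `ks_score`, `direction` (`up`/`down`), `p_raw`, `p_bonferroni`,
#'   `significant`, sorted by descending `ks_score` within cluster. The
#'   family size is attached as attribute `m_family`.
#' @export
cluster_markers <- function(expr, labels, alpha = 0.05,
                            family = c("global", "per_cluster")) {
  family <- match.arg(family)
  if (!all(colnames(expr) %in% labels$voxel_id)) {
    stop("labels do not cover all voxels in expr", call. = FALSE)
  }
  lab <- labels$cluster[match(colnames(expr), labels$voxel_id)]
  clusters <- sort(unique(lab))
  if (length(clusters) < 2L) stop("need >= 2 clusters", call. = FALSE)
  too_small <- clusters[tabulate(factor(lab, levels = clusters)) < 2L]
  if (length(too_small)) {
    stop("cluster(s) with fewer than 2 voxels: ",
         paste(too_small, collapse = ", "), call. = FALSE)
  }
  n_genes <- nrow(expr)
  m_family <- switch(family, per_cluster = n_genes,
                     global = n_genes * length(clusters))
  res <- purrr::map(clusters, function(cl) {
    in_cl <- lab == cl
    n_in <- sum(in_cl)
    n_out <- sum(!in_cl)
    x <- expr[, in_cl, drop = FALSE]
    y <- expr[, !in_cl, drop = FALSE]
    d <- vapply(seq_len(n_genes),
                function(g) .ks_stat(x[g, ], y[g, ]), numeric(1))
    ud <- unique(d)                       # memoize: D is heavily tied
    p <- ks_pvalue(ud, n_in, n_out)[match(d, ud)]
    med_diff <- unname(apply(x, 1, stats::median) - apply(y, 1, stats::median))
    tibble::tibble(
      cluster = cl,
      gene = rownames(expr),
      ks_score = d,
      direction = ifelse(med_diff < 0, "down", "up"),
      p_raw = p,
      p_bonferroni = pmin(1, p * m_family)
    )
  })
  out <- dplyr::bind_rows(res)
  out$significant <- out$p_bonferroni < alpha
  out <- dplyr::arrange(out, .data$cluster, dplyr::desc(.data$ks_score))
  attr(out, "m_family") <- m_family
  attr(out, "alpha") <- alpha
  class(out) <- c("marker_table", class(out))
  out
}

#' Filter markers for export
#'
#' Keeps, per cluster, the significant genes whose KS score exceeds the
#' threshold (strictly), the filter applied before exporting gene lists for
#' external functional-enrichment tools.
#'
#' @param table A `marker_table` from [cluster_markers()].
#' @param ks_threshold Minimum KS score (exclusive); default 0.25.
#' @return A named list (one element per cluster present in `table`) of
#'   character vectors of gene ids, ordered by descending KS score.
#' @export
filter_markers <- function(table, ks_threshold = 0.25) {
  keep <- table[table$significant & table$ks_score > ks_threshold, , drop = FALSE]
  keep <- keep[order(keep$cluster, -keep$ks_score), , drop = FALSE]
  clusters <- sort(unique(table$cluster))
  out <- lapply(clusters, function(cl) keep$gene[keep$cluster == cl])
  names(out) <- as.character(clusters)
  out
}

#' Write per-cluster marker gene lists
#'
#' One plain-text file per cluster (`cluster_<label>.txt`, one gene id per
#' line), the input format expected by external GO-enrichment tools.
#'
#' @param gene_lists Named list from [filter_markers()].
#' @param dir Output directory (created if absent).
#' @return The written paths, invisibly.
#' @export
write_marker_lists <- function(gene_lists, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(gene_lists), function(cl) {
    p <- file.path(dir, paste0("cluster_", cl, ".txt"))
    writeLines(gene_lists[[cl]], p)
    p
  }, character(1))
  invisible(paths)
}
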
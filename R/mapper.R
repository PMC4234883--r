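#' Standardize expression profiles
#'
#' Z-scores expression values prior to the norm-correlation metric. By
#' default each voxel's profile across genes is shifted and scaled to mean 0
#' and standard deviation 1 (population convention, divisor n), so that
#' Pearson correlation between voxels equals the uncentred cosine of their
#' z-profiles. Per-gene standardization across voxels is available via
#' `margin = "gene"`.
#'
#' @param expr Numeric matrix, genes x voxels (typically per-million values
#'   from [normalize_per_million()]).
#' @param margin `"voxel"` (default) standardizes each voxel column across
#'   genes; `"gene"` standardizes each gene row across voxels, silently
#'   dropping zero-variance genes.
#' @return A numeric matrix of the same orientation.
#' @export
standardize_profiles <- function(expr, margin = c("voxel", "gene")) {
  margin <- match.arg(margin)
  if (!is.matrix(expr) || nrow(expr) < 2L) {
    stop("expr must be a matrix with >= 2 genes", call. = FALSE)
  }
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  if (margin == "voxel") {
    mu <- colMeans(expr)
    sd <- sqrt(colMeans(expr^2) - mu^2)
    bad <- sd <= 0 | !is.finite(sd)
    if (any(bad)) {
      stop("voxel(s) with zero expression variance across genes: ",
           paste(utils::head(colnames(expr)[bad], 5), collapse = ", "),
           call. = FALSE)
    }
    sweep(sweep(expr, 2, mu, `-`), 2, sd, `/`)
  } else {
    mu <- rowMeans(expr)
    sd <- sqrt(rowMeans(expr^2) - mu^2)
    keep <- sd > 0 & is.finite(sd)
    if (!any(keep)) stop("all genes have zero variance", call. = FALSE)
    z <- sweep(sweep(expr[keep, , drop = FALSE], 1, mu[keep], `-`),
               1, sd[keep], `/`)
    z
  }
}

#' Pairwise norm-correlation distance
#'
#' The metric behind the topological clustering: `d(i, j) = 1 - r(i, j)`,
#' where `r` is the Pearson correlation between the standardized profiles of
#' voxels `i` and `j`. Distances lie in `[0, 2]` — 0 for identical profiles,
#' 2 for perfectly anti-correlated ones.
#'
#' @param standardized Matrix from [standardize_profiles()] (genes x voxels).
#' @return A symmetric n x n distance matrix with zero diagonal and voxel ids
#'   as dimnames.
#' @export
pairwise_norm_correlation <- function(standardized) {
  r <- stats::cor(standardized)
  if (any(!is.finite(r))) {
    stop("non-finite correlation; check for constant profiles", call. = FALSE)
  }
  d <- 1 - r
  d <- (d + t(d)) / 2           # enforce exact symmetry against fp noise
  d[d < 0] <- 0
  d[d > 2] <- 2
  diag(d) <- 0
  d
}

#' Metric SVD lens (classical multidimensional scaling)
#'
#' Computes the lens coordinates used to stratify voxels: classical MDS on
#' the norm-correlation distance matrix (double-centred `-D^2/2`, top-k
#' spectral coordinates ordered by decreasing eigenvalue). Lens 1 is the
#' principal metric-SVD coordinate, lens 2 the secondary. Signs are fixed so
#' that each coordinate's largest-magnitude entry is positive.
#'
#' @param D Symmetric distance matrix with voxel ids as dimnames.
#' @param k Number of lens coordinates; default 2.
#' @return A tibble with `voxel_id` and columns `lens_1` ... `lens_k`;
#'   eigenvalues attached as attribute `eigenvalues`.
#' @export
metric_svd_lens <- function(D, k = 2) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  n <- nrow(D)
  if (n < k + 1) stop("need at least k + 1 voxels", call. = FALSE)
  mds <- stats::cmdscale(D, k = k, eig = TRUE)
  ev <- mds$eig
  n_pos <- sum(ev > max(abs(ev)) * 1e-10)
  if (n_pos < k) {
    stop("only ", n_pos, " positive eigenvalue(s); use k <= ", n_pos,
         call. = FALSE)
  }
  pts <- mds$points
  if (ncol(pts) < k) stop("degenerate configuration; use smaller k", call. = FALSE)
  for (j in seq_len(k)) {
    if (pts[which.max(abs(pts[, j])), j] < 0) pts[, j] <- -pts[, j]
  }
  out <- tibble::tibble(voxel_id = if (is.null(rownames(D))) as.character(seq_len(n)) else rownames(D))
  for (j in seq_len(k)) out[[paste0("lens_", j)]] <- unname(pts[, j])
  attr(out, "eigenvalues") <- ev
  out
}

.base_intervals <- function(x, resolution, equalized) {
  n <- length(x)
  if (resolution < 1) stop("resolution must be >= 1", call. = FALSE)
  if (length(unique(x)) < resolution) {
    stop("resolution (", resolution, ") exceeds the number of distinct lens values (",
         length(unique(x)), ")", call. = FALSE)
  }
  if (equalized) {
    ord <- order(x, seq_along(x))   # stable tie-break by voxel index
    sizes <- rep(n %/% resolution, resolution)
    extra <- n %% resolution
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    ends <- cumsum(sizes)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    # breakpoints midway between adjacent quantile groups
    inner <- (x[ord[ends[-resolution]]] + x[ord[starts[-1L]]]) / 2
    lo <- c(min(x), inner)
    hi <- c(inner, max(x))
    tibble::tibble(
      bin = seq_len(resolution),
      lo = lo,
      hi = hi,
      n_base = sizes
    )
  } else {
    brk <- seq(min(x), max(x), length.out = resolution + 1L)
    lo <- utils::head(brk, -1L)
    hi <- utils::tail(brk, -1L)
    idx <- pmin(findInterval(x, brk, rightmost.closed = TRUE), resolution)
    tibble::tibble(bin = seq_len(resolution), lo = lo, hi = hi,
                   n_base = as.integer(tabulate(idx, resolution)))
  }
}

#' Build an overlapping cover of the lens space
#'
#' Per lens dimension, base intervals are equal-frequency (quantile)
#' partitions of the lens values into `resolution` bins (equal counts within
#' one voxel), then each interval is expanded about its centre to `gain`
#' times its base width. The two-dimensional cover is the Cartesian product
#' of the per-dimension interval lists; every voxel lies in at least one
#' product bin.
#'
#' @param lens Tibble from [metric_svd_lens()] with `lens_1`, `lens_2`, ...
#' @param resolution Integer vector, base intervals per lens dimension.
#' @param gain Numeric vector, overlap multiplier per dimension (>= 1).
#' @param equalized Use equal-frequency base intervals (default `TRUE`);
#'   `FALSE` gives equal-width intervals.
#' @return A `mapper_cover` object: per-dimension interval tables (`lo`,
#'   `hi` base bounds; `lo_exp`, `hi_exp` expanded bounds; `n_base` base
#'   occupancy) plus the parameters.
#' @seealso [bin_membership()]
#' @export
build_cover <- function(lens, resolution = c(40, 30), gain = c(2.5, 4.0),
                        equalized = TRUE) {
  dims <- grep("^lens_", names(lens), value = TRUE)
  nd <- length(dims)
  if (nd == 0L) stop("lens has no lens_* columns", call. = FALSE)
  resolution <- rep_len(as.integer(resolution), nd)
  gain <- rep_len(as.numeric(gain), nd)
  if (any(gain < 1)) stop("gain must be >= 1", call. = FALSE)
  ivs <- vector("list", nd)
  for (j in seq_len(nd)) {
    iv <- .base_intervals(lens[[dims[j]]], resolution[j], equalized)
    ctr <- (iv$lo + iv$hi) / 2
    hw <- gain[j] * (iv$hi - iv$lo) / 2
    iv$lo_exp <- ctr - hw
    iv$hi_exp <- ctr + hw
    ivs[[j]] <- iv
  }
  structure(
    list(dims = ivs, dim_names = dims, resolution = resolution, gain = gain,
         equalized = equalized),
    class = "mapper_cover"
  )
}

#' Bin membership under a cover
#'
#' Lists, for every voxel, the product bins of a cover it falls in (closed
#' expanded intervals per dimension, Cartesian product across dimensions).
#'
#' @param cover A `mapper_cover` from [build_cover()].
#' @param lens The lens tibble the cover was built from.
#' @return A tibble with one row per (voxel, bin) membership: `voxel_id`,
#'   `bin_id` (string `i.j` across dimensions), and per-dimension bin indices.
#' @export
bin_membership <- function(cover, lens) {
  nd <- length(cover$dims)
  per_dim <- vector("list", nd)
  for (j in seq_len(nd)) {
    x <- lens[[cover$dim_names[j]]]
    iv <- cover$dims[[j]]
    eps <- max(abs(iv$hi_exp - iv$lo_exp), 1) * 1e-9  # interval-edge fp guard
    per_dim[[j]] <- lapply(x, function(v) {
      iv$bin[v >= iv$lo_exp - eps & v <= iv$hi_exp + eps]
    })
  }
  rows <- vector("list", nrow(lens))
  for (i in seq_len(nrow(lens))) {
    combos <- expand.grid(lapply(per_dim, `[[`, i), KEEP.OUT.ATTRS = FALSE)
    names(combos) <- paste0("bin_", seq_len(nd))
    if (nrow(combos) == 0L) {
      stop("voxel ", lens$voxel_id[i], " falls in no cover bin", call. = FALSE)
    }
    combos$voxel_id <- lens$voxel_id[i]
    rows[[i]] <- combos
  }
  out <- dplyr::bind_rows(rows)
  out$bin_id <- do.call(paste, c(out[paste0("bin_", seq_len(nd))], sep = "."))
  tibble::as_tibble(out[, c("voxel_id", "bin_id", paste0("bin_", seq_len(nd)))])
}

#' Cluster the voxels of one cover bin
#'
#' Single-linkage clustering of a bin's members on the restricted distance
#' matrix, cut by the standard first-gap heuristic: merge heights are
#' histogrammed over `[0, max height]` with `histogram_bins` bins, and the
#' dendrogram is cut at the lower edge of the first empty bin that follows a
#' non-empty one. No such gap means the members form a single cluster.
#'
#' @param member_voxels Character vector of voxel ids in the bin.
#' @param D Full distance matrix with voxel ids as dimnames.
#' @param histogram_bins Number of histogram bins for the gap heuristic.
#' @return A list of character vectors, one per cluster.
#' @export
cluster_bin <- function(member_voxels, D, histogram_bins = 10) {
  m <- length(member_voxels)
  if (m == 0L) stop("empty bin", call. = FALSE)
  if (m == 1L) return(list(member_voxels))
  d_sub <- D[member_voxels, member_voxels, drop = FALSE]
  hc <- stats::hclust(stats::as.dist(d_sub), method = "single")
  h <- hc$height
  hmax <- max(h)
  if (hmax <= 0) return(list(member_voxels))
  brk <- seq(0, hmax, length.out = histogram_bins + 1L)
  counts <- graphics::hist(h, breaks = brk, plot = FALSE)$counts
  nonempty <- which(counts > 0)
  gap <- which(counts == 0 & seq_along(counts) > nonempty[1L])
  if (length(gap) == 0L) return(list(member_voxels))
  cut_h <- brk[gap[1L]]
  labs <- stats::cutree(hc, h = cut_h)
  unname(split(member_voxels, labs))
}

#' Build the nerve graph of a clustered cover
#'
#' One node per (bin, within-bin cluster); an undirected edge joins two
#' nodes exactly when their member sets share at least one voxel, weighted
#' by the shared count.
#'
#' @param bin_clusters Named list (by bin id) of partitions, each a list of
#'   character vectors as returned by [cluster_bin()].
#' @return A `mapper_graph`: list with tibbles `nodes` (`node_id`, `bin_id`,
#'   `members` list-column, `size`) and `edges` (`from`, `to`, `weight`).
#' @export
build_nerve <- function(bin_clusters) {
  nodes <- list()
  node_bin <- character()
  for (b in names(bin_clusters)) {
    for (cl in bin_clusters[[b]]) {
      if (length(cl) == 0L) next
      nodes[[length(nodes) + 1L]] <- cl
      node_bin <- c(node_bin, b)
    }
  }
  n_nodes <- length(nodes)
  node_tbl <- tibble::tibble(
    node_id = seq_len(n_nodes),
    bin_id = node_bin,
    members = nodes,
    size = lengths(nodes)
  )
  # invert membership: voxel -> nodes, then count co-occurrences
  vox <- unlist(nodes, use.names = FALSE)
  nid <- rep.int(seq_len(n_nodes), lengths(nodes))
  by_vox <- split(nid, vox)
  pair_keys <- unlist(lapply(by_vox, function(ns) {
    if (length(ns) < 2L) return(character())
    ns <- sort(ns)
    p <- utils::combn(ns, 2L)
    paste(p[1L, ], p[2L, ], sep = "_")
  }), use.names = FALSE)
  if (length(pair_keys)) {
    tab <- table(pair_keys)
    parts <- do.call(rbind, strsplit(names(tab), "_", fixed = TRUE))
    edges <- tibble::tibble(
      from = as.integer(parts[, 1L]),
      to = as.integer(parts[, 2L]),
      weight = as.integer(tab)
    )
    edges <- dplyr::arrange(edges, .data$from, .data$to)
  } else {
    edges <- tibble::tibble(from = integer(), to = integer(), weight = integer())
  }
  structure(list(nodes = node_tbl, edges = edges), class = "mapper_graph")
}

#' @exportS3Method base::print
print.mapper_graph <- function(x, ...) {
  cat("Mapper nerve graph: ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges, ", length(unique(unlist(x$nodes$members))), " voxels\n", sep = "")
  invisible(x)
}

.as_igraph <- function(graph) {
  g <- igraph::graph_from_data_frame(
    graph$edges,
    directed = FALSE,
    vertices = data.frame(name = as.character(graph$nodes$node_id))
  )
  g
}

.split_two <- function(g_sub) {
  comp <- igraph::components(g_sub)
  if (comp$no >= 2L) {
    small <- which.min(comp$csize)
    return(ifelse(comp$membership == small, 2L, 1L))
  }
  if (igraph::vcount(g_sub) < 2L) return(NULL)
  w <- igraph::E(g_sub)$weight
  cfg <- igraph::cluster_fast_greedy(g_sub, weights = w)
  if (length(cfg) >= 2L) {
    as.integer(igraph::cut_at(cfg, no = 2L))
  } else {
    # modularity refuses to split: peel off the weakest vertex
    m <- rep(1L, igraph::vcount(g_sub))
    m[which.min(igraph::strength(g_sub))] <- 2L
    m
  }
}

#' Segment the nerve graph into voxel clusters
#'
#' Groups nerve nodes into transcriptional clusters in two stages. First,
#' fine communities are found by deterministic modularity optimisation
#' (greedy agglomeration on the weighted nerve). Then, when the distance
#' matrix `D` is supplied (as [run_mapper()] does), the fine communities —
#' groups of samples already merged by the cover — are clustered by their
#' pairwise correlation distances: average-linkage agglomeration on the mean
#' norm-correlation distance between community voxel sets, cut at `k`, or,
#' for automatic `k`, just below the largest jump in merge height. This lets
#' communities that the lens placed in disconnected parts of the nerve join
#' the same transcriptional cluster. Without `D`, the fine communities are
#' themselves the segmentation, merged (smallest first, into the neighbour
#' community with the strongest total edge weight) or split (recursively,
#' largest first) to a requested `k`.
#'
#' Each voxel's label is the majority cluster of the nodes containing it;
#' ties go to the cluster holding the largest node, then to the lowest
#' cluster index.
#'
#' @param graph A `mapper_graph` from [build_nerve()].
#' @param k Target number of clusters, or `NULL` for automatic.
#' @param D Optional voxel distance matrix (dimnames = voxel ids) enabling
#'   the distance-refined segmentation.
#' @return A tibble `voxel_id`, `cluster` (integer labels `1..K`); node
#'   community assignments attached as attribute `node_communities`.
#' @export
segment_nerve <- function(graph, k = NULL, D = NULL) {
  n_nodes <- nrow(graph$nodes)
  if (n_nodes == 0L) stop("empty nerve graph", call. = FALSE)
  if (!is.null(k) && k > n_nodes) {
    stop("k (", k, ") exceeds the number of nerve nodes (", n_nodes, ")",
         call. = FALSE)
  }
  g <- .as_igraph(graph)
  if (igraph::ecount(g) > 0L) {
    cfg <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight)
    comm <- as.integer(igraph::membership(cfg))
  } else {
    comm <- seq_len(n_nodes)
  }

  comm_voxels <- function(comm) {
    vapply(sort(unique(comm)), function(cc) {
      length(unique(unlist(graph$nodes$members[comm == cc])))
    }, integer(1))
  }

  if (!is.null(D)) {
    comm <- .segment_by_distance(graph, comm, D, k)
  } else if (!is.null(k)) {
    # merge down
    while (length(unique(comm)) > k) {
      ids <- sort(unique(comm))
      sizes <- comm_voxels(comm)
      s <- ids[which.min(sizes)]
      w_to <- stats::setNames(numeric(length(ids)), ids)
      if (nrow(graph$edges)) {
        ca <- comm[graph$edges$from]
        cb <- comm[graph$edges$to]
        sel <- (ca == s) != (cb == s)
        other <- ifelse(ca[sel] == s, cb[sel], ca[sel])
        if (length(other)) {
          agg <- tapply(graph$edges$weight[sel], other, sum)
          w_to[names(agg)] <- agg
        }
      }
      w_to[as.character(s)] <- -Inf
      if (max(w_to) > 0) {
        target <- as.integer(names(w_to)[which.max(w_to)])
      } else {
        rest <- setdiff(ids, s)
        target <- rest[which.min(sizes[match(rest, ids)])]
      }
      comm[comm == s] <- target
    }
    # split up
    while (length(unique(comm)) < k) {
      ids <- sort(unique(comm))
      sizes <- comm_voxels(comm)
      done <- FALSE
      for (s in ids[order(-sizes)]) {
        members <- which(comm == s)
        g_sub <- igraph::induced_subgraph(g, members)
        sub_m <- .split_two(g_sub)
        if (!is.null(sub_m) && length(unique(sub_m)) == 2L) {
          new_id <- max(comm) + 1L
          comm[members[sub_m == 2L]] <- new_id
          done <- TRUE
          break
        }
      }
      if (!done) stop("cannot split communities further to reach k = ", k,
                      call. = FALSE)
    }
  }

  # canonical labels 1..K, ordered by first node appearance
  comm <- match(comm, unique(comm[order(seq_len(n_nodes))]))

  .vote_voxels(graph, comm)
}

# agglomerate fine communities on mean voxel-pair distance (average linkage);
# automatic k cuts just below the largest merge-height jump
.segment_by_distance <- function(graph, fine, D, k) {
  fine <- match(fine, sort(unique(fine)))
  nb <- max(fine)
  if (!is.null(k) && k > nb) {
    # finer targets than the community count: agglomerate the nodes directly
    fine <- seq_len(nrow(graph$nodes))
    nb <- length(fine)
  }
  if (nb == 1L) return(rep(1L, length(fine)))
  blocks <- lapply(seq_len(nb), function(b) {
    unique(unlist(graph$nodes$members[fine == b]))
  })
  bd <- matrix(0, nb, nb)
  for (i in seq_len(nb - 1L)) {
    for (j in (i + 1L):nb) {
      bd[i, j] <- bd[j, i] <- mean(D[blocks[[i]], blocks[[j]]])
    }
  }
  hc <- stats::hclust(stats::as.dist(bd), method = "average",
                      members = lengths(blocks))
  if (is.null(k)) {
    jumps <- diff(hc$height)
    k <- if (length(jumps) == 0L) nb - 1L else nb - which.max(jumps)
  }
  blk_cl <- stats::cutree(hc, k = k)
  blk_cl[fine]
}

.vote_voxels <- function(graph, comm) {
  n_nodes <- nrow(graph$nodes)

  # voxel labels by majority vote over containing nodes
  vox <- unlist(graph$nodes$members, use.names = FALSE)
  nid <- rep.int(seq_len(n_nodes), lengths(graph$nodes$members))
  by_vox <- split(nid, vox)
  label_of <- vapply(by_vox, function(ns) {
    cc <- comm[ns]
    tab <- table(cc)
    winners <- as.integer(names(tab)[tab == max(tab)])
    if (length(winners) == 1L) return(winners)
    cand <- ns[comm[ns] %in% winners]
    sizes <- graph$nodes$size[cand]
    top <- cand[sizes == max(sizes)]
    min(comm[top])
  }, integer(1))
  out <- tibble::tibble(voxel_id = names(by_vox), cluster = unname(label_of))
  out <- dplyr::arrange(out, .data$voxel_id)
  attr(out, "node_communities") <- comm
  out
}

#' Run the full topological clustering pipeline
#'
#' Composes the whole Mapper construction with the analysis defaults:
#' per-voxel standardization, norm-correlation metric, two metric-SVD
#' lenses, equalized covers at resolution (40, 30) with gain (2.5x, 4x),
#' single-linkage clustering within bins, the nerve graph, and modularity
#' segmentation into voxel clusters.
#'
#' @param expr Numeric expression matrix, genes x voxels (per-million
#'   values).
#' @param resolution,gain,equalized Cover parameters per lens dimension; see
#'   [build_cover()].
#' @param k Target cluster count for [segment_nerve()], or `NULL` for
#'   automatic.
#' @param histogram_bins Gap-heuristic bins for [cluster_bin()].
#' @param standardize Standardization margin, see [standardize_profiles()].
#' @param seed Optional integer; the pipeline is deterministic, but a seed is
#'   applied around segmentation so stochastic community methods plugged in
#'   later stay reproducible.
#' @return A `mapper_fit` object: lens tibble, `mapper_cover`, the
#'   `mapper_graph`, a labels tibble (`voxel_id`, `cluster`), and the
#'   parameters. Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @export
run_mapper <- function(expr, resolution = c(40, 30), gain = c(2.5, 4.0),
                       equalized = TRUE, k = NULL, histogram_bins = 10,
                       standardize = c("voxel", "gene"), seed = NULL) {
  standardize <- match.arg(standardize)
  z <- standardize_profiles(expr, margin = standardize)
  D <- pairwise_norm_correlation(z)
  lens <- metric_svd_lens(D, k = 2)
  cover <- build_cover(lens, resolution = resolution, gain = gain,
                       equalized = equalized)
  membership <- bin_membership(cover, lens)
  bins <- split(membership$voxel_id, membership$bin_id)
  bin_clusters <- lapply(bins, cluster_bin, D = D,
                         histogram_bins = histogram_bins)
  graph <- build_nerve(bin_clusters)
  labels <- if (is.null(seed)) {
    segment_nerve(graph, k = k, D = D)
  } else {
    withr::with_seed(seed, segment_nerve(graph, k = k, D = D))
  }
  structure(
    list(lens = lens, cover = cover, graph = graph, labels = labels,
         distances = D,
         params = list(resolution = resolution, gain = gain,
                       equalized = equalized, k = k,
                       histogram_bins = histogram_bins,
                       standardize = standardize, seed = seed)),
    class = "mapper_fit"
  )
}

#' @exportS3Method base::print
print.mapper_fit <- function(x, ...) {
  cat("Mapper fit\n")
  cat("  voxels:   ", nrow(x$labels), "\n", sep = "")
  cat("  nodes:    ", nrow(x$graph$nodes), "\n", sep = "")
  cat("  edges:    ", nrow(x$graph$edges), "\n", sep = "")
  cat("  clusters: ", length(unique(x$labels$cluster)), "\n", sep = "")
  cat("  cover:    resolution (",
      paste(x$params$resolution, collapse = ", "), "), gain (",
      paste(x$params$gain, collapse = ", "), "), ",
      if (x$params$equalized) "equalized" else "equal-width", "\n", sep = "")
  invisible(x)
}
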
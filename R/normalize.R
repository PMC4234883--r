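#' Normalize counts to reads per million
#'
#' Converts raw voxel counts to per-million expression values: each gene's
#' count is divided by the voxel's total over included genes and scaled by
#' 1e6, so every voxel column of the result sums to one million. Genes on the
#' exclusion list (typically repeat elements) are removed from both the
#' scaling denominator and the output.
#'
#' @param counts Integer count matrix, genes x voxels, with dimnames.
#' @param exclude Character vector of gene ids to exclude; must all be present
#'   in `counts`. Default none.
#' @return A numeric matrix of per-million values (included genes x voxels)
#'   with attribute `excluded_genes`. Voxels whose included total is zero get
#'   an all-zero column and a warning.
#' @examples
#' m <- matrix(c(10L, 90L), 2, 1, dimnames = list(c("a", "b"), "v1"))
#' normalize_per_million(m)
#' @export
normalize_per_million <- function(counts, exclude = character()) {
  validate_count_matrix(counts)
  exclude <- unique(as.character(exclude))
  unknown <- setdiff(exclude, rownames(counts))
  if (length(unknown)) {
    stop("exclusion list contains unknown gene id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  keep <- setdiff(rownames(counts), exclude)
  if (length(keep) == 0L) {
    stop("exclusion list removes all genes", call. = FALSE)
  }
  kept <- counts[keep, , drop = FALSE]
  totals <- colSums(kept)
  zero <- totals == 0
  if (any(zero)) {
    warning("voxel(s) with zero included reads set to all-zero: ",
            paste(utils::head(colnames(kept)[zero], 5), collapse = ", "),
            if (sum(zero) > 5) ", ..." else "", call. = FALSE)
  }
  scale <- ifelse(zero, 0, 1e6 / totals)
  values <- sweep(kept, 2, scale, `*`)
  storage.mode(values) <- "double"
  attr(values, "excluded_genes") <- exclude
  values
}

#' Detected genes per voxel
#'
#' Counts, for each voxel, the genes with at least `min_reads` reads. The
#' returned tibble carries the per-study summaries as attributes:
#' `mean_detected` (average detected genes per voxel) and `union_detected`
#' (genes detected in at least one voxel).
#'
#' @param counts Integer count matrix, genes x voxels.
#' @param min_reads Detection threshold in reads; default 1.
#' @return A tibble with columns `voxel_id` and `n_detected`.
#' @export
detected_genes_per_voxel <- function(counts, min_reads = 1) {
  validate_count_matrix(counts)
  if (min_reads < 1) stop("min_reads must be >= 1", call. = FALSE)
  hit <- counts >= min_reads
  out <- tibble::tibble(
    voxel_id = colnames(counts),
    n_detected = as.integer(colSums(hit))
  )
  attr(out, "mean_detected") <- mean(out$n_detected)
  attr(out, "union_detected") <- sum(rowSums(hit) > 0)
  out
}
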
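# small in-code fixtures shared across test files

`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_counts <- function(values, genes = NULL, voxels = NULL) {
  m <- matrix(as.integer(values),
              nrow = if (is.null(genes)) 2 else length(genes))
  rownames(m) <- genes %||% paste0("g", seq_len(nrow(m)))
  colnames(m) <- voxels %||% paste0("v", seq_len(ncol(m)))
  m
}

random_counts <- function(n_genes, n_voxels, seed, max_count = 50) {
  withr::with_seed(seed, {
    m <- matrix(sample.int(max_count + 1L, n_genes * n_voxels, replace = TRUE) - 1L,
                n_genes, n_voxels)
    dimnames(m) <- list(sprintf("g%03d", seq_len(n_genes)),
                        sprintf("v%03d", seq_len(n_voxels)))
    m
  })
}

tiny_layout <- function(n, section = "S1") {
  g <- tibble::tibble(
    voxel_id = paste0("v", seq_len(n)),
    section_id = section,
    row = (seq_len(n) - 1L) %/% 4L,
    col = (seq_len(n) - 1L) %% 4L
  )
  attr(g, "pitch_um") <- 50
  g
}

# independent brute-force KS oracle: max ECDF difference at pooled values
ks_oracle <- function(x, y) {
  at <- sort(unique(c(x, y)))
  max(abs(stats::ecdf(x)(at) - stats::ecdf(y)(at)))
}

# brute-force pair-counting ARI oracle
ari_oracle <- function(a, b) {
  n <- length(a)
  s00 <- s11 <- s01 <- s10 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) s11 <- s11 + 1
      else if (sa && !sb) s10 <- s10 + 1
      else if (!sa && sb) s01 <- s01 + 1
      else s00 <- s00 + 1
    }
  }
  tot <- s11 + s10 + s01 + s00
  exp_idx <- (s11 + s10) * (s11 + s01) / tot
  max_idx <- ((s11 + s10) + (s11 + s01)) / 2
  if (max_idx == exp_idx) return(1)
  (s11 - exp_idx) / (max_idx - exp_idx)
}
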
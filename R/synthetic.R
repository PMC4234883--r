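#' Configuration for the synthetic voxel generator
#'
#' Defines the study-like conditions the generator emulates: a wedge-shaped
#' tissue mask on a regular grid (the largest section in the data regime is
#' ~130 voxels of ~100 cells each), five expression programs arranged in four
#' dorsoventral bands — program 1 in the dorsal (ventricular-zone-like) band,
#' programs 2 and 3 in successive bands, programs 4 and 5 interleaved at
#' random voxel-by-voxel within the ventral-most band — log-normal baseline
#' abundances and library sizes, negative-binomial counting noise and
#' dropout.
#'
#' @param rows,cols Grid dimensions; default 16 x 12.
#' @param mask_fraction Fraction of the grid covered by the wedge mask;
#'   default 0.65 (~130 voxels on the default grid).
#' @param mask_shape `"wedge"` (default, the tissue-like mask) or
#'   `"rectangle"` (every grid position a voxel; `mask_fraction` ignored).
#' @param n_genes Number of genes; default 2000.
#' @param n_programs Number of expression programs; default 5 (in 4 bands).
#' @param markers_per_program Marker genes per program; default 200 (a tenth
#'   of the genes per program, the breadth of a zonal expression program
#'   rather than a handful of sentinel genes).
#' @param effect_log2 log2 fold-change of a marker inside its program's
#'   voxels; default 2 (4-fold).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of relative
#'   gene abundance; defaults 0 and 1.0.
#' @param library_meanlog,library_sdlog Log-normal parameters of per-voxel
#'   library size (reads); defaults log(14000) and 0.6 — heavy-tailed depths
#'   that keep the mean reads per gene per voxel (~7) at the study scale
#'   once the gene panel is reduced to desk size.
#' @param dispersion Negative-binomial size parameter; default 10 (a ~100-cell
#'   voxel behaves like a small bulk sample, with modest overdispersion).
#' @param dropout Probability that an observed count is zeroed; default 0.05
#'   (pooled voxels show little of the dropout seen in single cells).
#' @param seed Mandatory integer seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(rows = 16, cols = 12, mask_fraction = 0.65,
                             mask_shape = c("wedge", "rectangle"),
                             n_genes = 2000, n_programs = 5,
                             markers_per_program = 200, effect_log2 = 2,
                             baseline_meanlog = 0, baseline_sdlog = 1.0,
                             library_meanlog = log(14000), library_sdlog = 0.6,
                             dispersion = 10, dropout = 0.05, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  mask_shape <- match.arg(mask_shape)
  stopifnot(rows >= 4, cols >= 1, mask_fraction > 0, mask_fraction <= 1,
            n_genes >= 1, n_programs >= 1, markers_per_program >= 1,
            n_programs * markers_per_program <= n_genes,
            baseline_sdlog > 0, library_sdlog >= 0, dispersion > 0,
            dropout >= 0, dropout < 1)
  structure(
    list(rows = as.integer(rows), cols = as.integer(cols),
         mask_fraction = mask_fraction, mask_shape = mask_shape,
         n_genes = as.integer(n_genes),
         n_programs = as.integer(n_programs),
         markers_per_program = as.integer(markers_per_program),
         effect_log2 = effect_log2, baseline_meanlog = baseline_meanlog,
         baseline_sdlog = baseline_sdlog, library_meanlog = library_meanlog,
         library_sdlog = library_sdlog, dispersion = dispersion,
         dropout = dropout, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# wedge mask: width grows ventrally (downward), columns centred
.wedge_mask <- function(config) {
  if (identical(config$mask_shape, "rectangle")) {
    g <- expand.grid(col = seq_len(config$cols) - 1L,
                     row = seq_len(config$rows) - 1L)
    return(tibble::tibble(row = as.integer(g$row), col = as.integer(g$col)))
  }
  widths <- pmax(1L, pmin(config$cols, round(
    config$cols * seq(0.3, 1, length.out = config$rows) *
      (config$mask_fraction / 0.65)
  )))
  rows <- integer()
  cols <- integer()
  for (r in seq_len(config$rows)) {
    w <- widths[r]
    start <- floor((config$cols - w) / 2)
    rows <- c(rows, rep.int(r - 1L, w))
    cols <- c(cols, start + seq_len(w) - 1L)
  }
  tibble::tibble(row = as.integer(rows), col = as.integer(cols))
}

# split mask rows into 4 contiguous dorsoventral bands of near-equal voxels
.band_of <- function(mask_rows) {
  n <- length(mask_rows)
  ur <- sort(unique(mask_rows))
  if (length(ur) < 4L) {
    stop("mask too small for the 4-band structure (needs >= 4 rows)",
         call. = FALSE)
  }
  cum <- cumsum(as.integer(table(factor(mask_rows, levels = ur))))
  bounds <- vapply(1:3, function(q) ur[which(cum >= q * n / 4)[1L]], numeric(1))
  band <- findInterval(mask_rows, c(-Inf, bounds + 0.5, Inf))
  if (length(unique(band)) < 4L) {
    stop("mask too small for the 4-band structure (an empty band)",
         call. = FALSE)
  }
  band
}

.layout_tibble <- function(mask) {
  grid <- tibble::tibble(
    voxel_id = sprintf("v%03d", seq_len(nrow(mask))),
    section_id = "S1",
    row = mask$row,
    col = mask$col
  )
  attr(grid, "pitch_um") <- 50
  grid
}

#' Generate a synthetic voxel fixture with planted spatial programs
#'
#' Draws a genes x voxels count matrix under the configured conditions:
#' marker genes are amplified `2^effect_log2`-fold in their program's
#' voxels, per-voxel means are scaled (thinned) to a log-normal library
#' size, counts are negative-binomial, and a dropout fraction of entries is
#' zeroed. Deterministic given `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return A list: `counts` (integer matrix), `grid` (layout tibble),
#'   `truth` (tibble `voxel_id`, `program`), `marker_genes` (tibble `gene`,
#'   `program`), and `config`.
#' @export
generate_fixture <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  mask <- .wedge_mask(config)
  band <- .band_of(mask$row)
  grid <- .layout_tibble(mask)
  n_vox <- nrow(grid)
  withr::with_seed(config$seed, {
    program <- band
    ventral <- band == 4L
    if (config$n_programs >= 5L) {
      program[ventral] <- sample(c(4L, 5L), sum(ventral), replace = TRUE)
    }
    lambda <- stats::rlnorm(config$n_genes, config$baseline_meanlog,
                            config$baseline_sdlog)
    marker_idx <- sample.int(config$n_genes,
                             config$n_programs * config$markers_per_program)
    marker_program <- rep(seq_len(config$n_programs),
                          each = config$markers_per_program)
    mu <- matrix(lambda, config$n_genes, n_vox)
    fold <- 2^config$effect_log2
    for (p in seq_len(config$n_programs)) {
      vp <- program == p
      if (any(vp)) {
        mu[marker_idx[marker_program == p], vp] <-
          mu[marker_idx[marker_program == p], vp, drop = FALSE] * fold
      }
    }
    lib <- stats::rlnorm(n_vox, config$library_meanlog, config$library_sdlog)
    mu <- sweep(mu, 2, lib / colSums(mu), `*`)
    counts <- matrix(
      stats::rnbinom(length(mu), mu = mu, size = config$dispersion),
      config$n_genes, n_vox
    )
    if (config$dropout > 0) {
      drop <- matrix(stats::runif(length(counts)) < config$dropout,
                     config$n_genes, n_vox)
      counts[drop] <- 0L
    }
    storage.mode(counts) <- "integer"
    dimnames(counts) <- list(sprintf("g%04d", seq_len(config$n_genes)),
                             grid$voxel_id)
    list(
      counts = counts,
      grid = grid,
      truth = tibble::tibble(voxel_id = grid$voxel_id, program = program),
      marker_genes = tibble::tibble(gene = rownames(counts)[marker_idx],
                                    program = marker_program),
      config = config
    )
  })
}

#' Generate null voxel data with no spatial structure
#'
#' Counts are i.i.d. across voxels (same negative-binomial gene means
#' everywhere, no programs), for family-wise-error checks of the marker
#' tests. A fixed arbitrary partition of the voxels into 4 near-equal groups
#' (round-robin by voxel index, sizes differing by at most 1) is returned as
#' the null "clustering".
#'
#' @param config A [synthetic_config()].
#' @return A list: `counts`, `grid`, `partition` (tibble `voxel_id`,
#'   `cluster`), and `config`.
#' @export
generate_null <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  mask <- .wedge_mask(config)
  grid <- .layout_tibble(mask)
  n_vox <- nrow(grid)
  withr::with_seed(config$seed, {
    lambda <- stats::rlnorm(config$n_genes, config$baseline_meanlog,
                            config$baseline_sdlog)
    lib <- exp(config$library_meanlog + config$library_sdlog^2 / 2)
    mu <- lambda / sum(lambda) * lib
    counts <- matrix(
      stats::rnbinom(config$n_genes * n_vox, mu = mu, size = config$dispersion),
      config$n_genes, n_vox
    )
    if (config$dropout > 0) {
      drop <- matrix(stats::runif(length(counts)) < config$dropout,
                     config$n_genes, n_vox)
      counts[drop] <- 0L
    }
    storage.mode(counts) <- "integer"
    dimnames(counts) <- list(sprintf("g%04d", seq_len(config$n_genes)),
                             grid$voxel_id)
    list(
      counts = counts,
      grid = grid,
      partition = tibble::tibble(voxel_id = grid$voxel_id,
                                 cluster = rep_len(1:4, n_vox)),
      config = config
    )
  })
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement computed from the contingency table by the
#' standard permutation-model formula.
#'
#' @param a,b Vectors of labels over the same items.
#' @return ARI in `[-1, 1]`; 1 for identical partitions, ~0 at chance.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions differ in length", call. = FALSE)
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(1)      # both partitions trivial and identical
  (sum_ij - expected) / denom
}

#' Score cluster recovery against planted truth
#'
#' @param labels Tibble `voxel_id`, `cluster` (recovered).
#' @param truth Tibble `voxel_id`, second column the planted labels.
#' @return The adjusted Rand index.
#' @export
evaluate_recovery <- function(labels, truth) {
  if (!setequal(labels$voxel_id, truth$voxel_id)) {
    stop("voxel ids of labels and truth differ", call. = FALSE)
  }
  m <- match(labels$voxel_id, truth$voxel_id)
  adjusted_rand_index(labels$cluster, truth[[2L]][m])
}
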
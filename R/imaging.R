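#' Back-project a gene onto the section grid
#'
#' Builds the raster image of one gene in one section: pixel (row, col) holds
#' the gene's per-million value in the voxel at that grid position, and
#' positions without a voxel are background (`NA`). One voxel maps to exactly
#' one pixel; no interpolation or smoothing is ever applied.
#'
#' @param expr Numeric expression matrix, genes x voxels.
#' @param grid Voxel layout tibble (see [read_voxel_layout()]).
#' @param gene Gene id to project.
#' @param section Section id to project onto.
#' @return A `voxel_image` with `values` (rows x cols matrix over the
#'   section's bounding box), `kind = "continuous"`, the section id, grid
#'   offsets and pitch.
#' @export
project_gene <- function(expr, grid, gene, section) {
  if (!gene %in% rownames(expr)) stop("unknown gene: ", gene, call. = FALSE)
  sec <- grid[grid$section_id == section, , drop = FALSE]
  if (nrow(sec) == 0L) stop("unknown section: ", section, call. = FALSE)
  vals <- expr[gene, match(sec$voxel_id, colnames(expr))]
  if (anyNA(vals)) {
    stop("section voxel(s) absent from expr: ",
         paste(utils::head(sec$voxel_id[is.na(vals)], 5), collapse = ", "),
         call. = FALSE)
  }
  .voxel_image(sec, vals, kind = "continuous", label = gene,
               pitch_um = attr(grid, "pitch_um") %||% 50)
}

#' Back-project cluster labels onto the section grid
#'
#' Categorical counterpart of [project_gene()]: pixel (row, col) holds the
#' cluster label of the voxel at that position. A contiguity report —
#' the number of 4-connected components each label forms within the tissue
#' mask — is attached, quantifying whether clusters occupy spatially
#' distinct regions.
#'
#' @param labels Tibble `voxel_id`, `cluster` (e.g. from [run_mapper()]).
#' @param grid Voxel layout tibble.
#' @param section Section id.
#' @return A `voxel_image` with `kind = "categorical"` and a `contiguity`
#'   tibble (`cluster`, `n_components`).
#' @export
project_clusters <- function(labels, grid, section) {
  sec <- grid[grid$section_id == section, , drop = FALSE]
  if (nrow(sec) == 0L) stop("unknown section: ", section, call. = FALSE)
  lab <- labels$cluster[match(sec$voxel_id, labels$voxel_id)]
  if (anyNA(lab)) {
    stop("unlabeled voxel(s) in section ", section, ": ",
         paste(utils::head(sec$voxel_id[is.na(lab)], 5), collapse = ", "),
         call. = FALSE)
  }
  img <- .voxel_image(sec, lab, kind = "categorical", label = "cluster",
                      pitch_um = attr(grid, "pitch_um") %||% 50)
  img$contiguity <- .contiguity_report(img$values)
  img
}

.voxel_image <- function(sec, vals, kind, label, pitch_um) {
  r0 <- min(sec$row)
  c0 <- min(sec$col)
  nr <- max(sec$row) - r0 + 1L
  nc <- max(sec$col) - c0 + 1L
  m <- matrix(NA_real_, nr, nc)
  m[cbind(sec$row - r0 + 1L, sec$col - c0 + 1L)] <- vals
  vox <- matrix(NA_character_, nr, nc)
  vox[cbind(sec$row - r0 + 1L, sec$col - c0 + 1L)] <- sec$voxel_id
  structure(
    list(section_id = sec$section_id[[1L]], values = m, voxel_ids = vox,
         kind = kind, label = label, row_offset = r0, col_offset = c0,
         pitch_um = pitch_um),
    class = "voxel_image"
  )
}

# 4-connected components per label on a label matrix with NA background
.contiguity_report <- function(m) {
  nr <- nrow(m)
  nc <- ncol(m)
  comp <- matrix(0L, nr, nc)
  next_comp <- 0L
  comp_label <- integer()
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (is.na(m[i, j]) || comp[i, j] != 0L) next
      next_comp <- next_comp + 1L
      comp_label <- c(comp_label, m[i, j])
      queue <- list(c(i, j))
      comp[i, j] <- next_comp
      while (length(queue)) {
        cur <- queue[[length(queue)]]
        queue[[length(queue)]] <- NULL
        for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
          ni <- cur[1L] + d[1L]
          nj <- cur[2L] + d[2L]
          if (ni >= 1L && ni <= nr && nj >= 1L && nj <= nc &&
              !is.na(m[ni, nj]) && comp[ni, nj] == 0L &&
              m[ni, nj] == m[cur[1L], cur[2L]]) {
            comp[ni, nj] <- next_comp
            queue[[length(queue) + 1L]] <- c(ni, nj)
          }
        }
      }
    }
  }
  tb <- table(comp_label)
  tibble::tibble(
    cluster = as.numeric(names(tb)),
    n_components = as.integer(tb)
  )
}

#' @exportS3Method base::print
print.voxel_image <- function(x, ...) {
  cat("voxel image (", x$kind, "): section ", x$section_id, ", ",
      nrow(x$values), " x ", ncol(x$values), " grid, ",
      sum(!is.na(x$values)), " tissue voxels, ", x$label, "\n", sep = "")
  if (!is.null(x$contiguity)) {
    cat("  4-connected components per cluster: ",
        paste(x$contiguity$cluster, x$contiguity$n_components,
              sep = ":", collapse = "  "), "\n", sep = "")
  }
  invisible(x)
}

#' Render a voxel image to PNG
#'
#' Writes the image as a PNG with each voxel drawn as a `scale x scale`
#' pixel block. Continuous values are mapped through the inferno colormap,
#' scaled to the image maximum by default or to a fixed `zlim`; categorical
#' labels use the Okabe-Ito palette (recycled beyond 9 labels). Background
#' (non-tissue) pixels are black. Output bytes are deterministic for
#' identical inputs.
#'
#' @param image A `voxel_image`.
#' @param path Output PNG path.
#' @param scale Integer pixel block size per voxel (>= 1).
#' @param zlim Optional `c(min, max)` for continuous images (fixed scale
#'   across images); default per-image `c(0, max)`.
#' @return `path`, invisibly.
#' @export
render_png <- function(image, path, scale = 1, zlim = NULL) {
  if (scale < 1) stop("scale must be >= 1", call. = FALSE)
  cols <- image_colors(image, zlim = zlim)
  rgb <- grDevices::col2rgb(cols) / 255
  nr <- nrow(image$values)
  nc <- ncol(image$values)
  arr <- array(0, dim = c(nr, nc, 3))
  for (ch in 1:3) arr[, , ch] <- matrix(rgb[ch, ], nr, nc)
  if (scale > 1) {
    arr <- arr[rep(seq_len(nr), each = scale),
               rep(seq_len(nc), each = scale), , drop = FALSE]
  }
  png::writePNG(arr, path)
  invisible(path)
}

#' Color mapping for a voxel image
#'
#' The documented colormap used by [render_png()] and [autoplot.voxel_image()]:
#' inferno (256 levels, low = dark) for continuous values, Okabe-Ito for
#' categorical labels, black background.
#'
#' @param image A `voxel_image`.
#' @param zlim Optional fixed range for continuous images.
#' @return Character matrix of hex colors, same shape as `image$values`.
#' @export
image_colors <- function(image, zlim = NULL) {
  v <- image$values
  bg <- "#000000"
  if (image$kind == "continuous") {
    ramp <- grDevices::hcl.colors(256, "Inferno")
    if (is.null(zlim)) zlim <- c(0, max(v, na.rm = TRUE))
    if (zlim[2] <= zlim[1]) zlim[2] <- zlim[1] + 1
    idx <- pmin(255, pmax(0, floor((v - zlim[1]) / (zlim[2] - zlim[1]) * 255)))
    cols <- ramp[idx + 1]
  } else {
    pal <- grDevices::palette.colors(9, "Okabe-Ito")
    cols <- pal[((as.integer(v) - 1L) %% 9L) + 1L]
  }
  cols[is.na(v)] <- bg
  matrix(cols, nrow(v), ncol(v))
}

#' Look up the voxel behind a pixel
#'
#' Inverse of the back-projection on the tissue mask: returns the voxel id
#' at image position (row, col), or `NA` for background.
#'
#' @param image A `voxel_image`.
#' @param row,col 1-based position within the image array.
#' @return The voxel id, or `NA_character_`.
#' @export
pixel_voxel <- function(image, row, col) {
  image$voxel_ids[row, col]
}
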
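#' Read a genes-by-voxels count matrix
#'
#' Reads a raw count matrix from disk. Two formats are supported:
#' \describe{
#'   \item{`tsv`}{Tab-separated, UTF-8, no quoting. Row 1 is a header whose
#'     first cell is the literal `gene` followed by voxel ids; each further
#'     row is a gene id followed by non-negative integer counts.}
#'   \item{`mtx`}{MatrixMarket sparse matrix accompanied by two sidecar
#'     files, `<path minus .mtx>.genes.txt` and `<path minus .mtx>.voxels.txt`,
#'     holding one id per line (genes = rows, voxels = columns).}
#' }
#'
#' @param path Path to the matrix file.
#' @param format One of `"tsv"` or `"mtx"`.
#' @return An integer matrix with gene ids as row names and voxel ids as
#'   column names, in file order.
#' @seealso [write_count_matrix()], [read_voxel_layout()], [align_voxels()]
#' @export
read_count_matrix <- function(path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("count matrix file not found: ", path, call. = FALSE)
  }
  counts <- switch(format,
    tsv = .read_counts_tsv(path),
    mtx = .read_counts_mtx(path)
  )
  validate_count_matrix(counts)
  counts
}

.read_counts_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 1L || !nzchar(lines[[1L]])) {
    stop("malformed header: line 1 is empty in ", path, call. = FALSE)
  }
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L) {
    stop("malformed header (line 1): expected 'gene' plus voxel ids", call. = FALSE)
  }
  voxel_ids <- header[-1L]
  if (anyDuplicated(voxel_ids)) {
    stop("duplicate voxel id in header (line 1): ",
         voxel_ids[duplicated(voxel_ids)][1L], call. = FALSE)
  }
  body <- lines[-1L]
  body <- body[nzchar(body)]
  n_vox <- length(voxel_ids)
  gene_ids <- character(length(body))
  counts <- matrix(0L, nrow = length(body), ncol = n_vox)
  for (i in seq_along(body)) {
    fields <- strsplit(body[[i]], "\t", fixed = TRUE)[[1L]]
    line_no <- i + 1L
    if (length(fields) != n_vox + 1L) {
      stop("line ", line_no, ": expected ", n_vox + 1L, " fields, found ",
           length(fields), call. = FALSE)
    }
    gene_ids[[i]] <- fields[[1L]]
    vals <- fields[-1L]
    if (any(grepl("^-", vals))) {
      stop("line ", line_no, ": negative count for gene '", fields[[1L]], "'",
           call. = FALSE)
    }
    if (!all(grepl("^[0-9]+$", vals))) {
      bad <- vals[!grepl("^[0-9]+$", vals)][1L]
      stop("line ", line_no, ": non-integer count '", bad, "'", call. = FALSE)
    }
    counts[i, ] <- as.integer(vals)
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene id: ", gene_ids[duplicated(gene_ids)][1L], call. = FALSE)
  }
  dimnames(counts) <- list(gene_ids, voxel_ids)
  counts
}

.mtx_sidecars <- function(path) {
  stem <- sub("\\.mtx$", "", path)
  list(genes = paste0(stem, ".genes.txt"), voxels = paste0(stem, ".voxels.txt"))
}

.read_counts_mtx <- function(path) {
  side <- .mtx_sidecars(path)
  for (f in unlist(side)) {
    if (!file.exists(f)) stop("missing MTX sidecar file: ", f, call. = FALSE)
  }
  m <- as.matrix(Matrix::readMM(path))
  gene_ids <- readLines(side$genes)
  voxel_ids <- readLines(side$voxels)
  if (nrow(m) != length(gene_ids) || ncol(m) != length(voxel_ids)) {
    stop("MTX dimensions (", nrow(m), "x", ncol(m),
         ") do not match sidecar id counts (", length(gene_ids), ", ",
         length(voxel_ids), ")", call. = FALSE)
  }
  if (any(m < 0)) stop("negative count in ", path, call. = FALSE)
  if (any(m != round(m))) stop("non-integer count in ", path, call. = FALSE)
  storage.mode(m) <- "integer"
  dimnames(m) <- list(gene_ids, voxel_ids)
  m
}

#' Write a count matrix
#'
#' Inverse of [read_count_matrix()]; the TSV dialect round-trips
#' byte-identically (tab-separated, header cell `gene`, no quoting).
#'
#' @param counts Integer matrix, genes x voxels, with dimnames.
#' @param path Output path.
#' @param format One of `"tsv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  validate_count_matrix(counts)
  if (format == "tsv") {
    header <- paste(c("gene", colnames(counts)), collapse = "\t")
    rows <- vapply(seq_len(nrow(counts)), function(i) {
      paste(c(rownames(counts)[i], counts[i, ]), collapse = "\t")
    }, character(1))
    writeLines(c(header, rows), path, useBytes = TRUE)
  } else {
    side <- .mtx_sidecars(path)
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    writeLines(rownames(counts), side$genes)
    writeLines(colnames(counts), side$voxels)
  }
  invisible(path)
}

#' Validate a count matrix
#'
#' Checks the invariants every count matrix in the pipeline must satisfy:
#' unique gene and voxel ids, integral non-negative entries, consistent
#' dimensions.
#'
#' @param counts Matrix to check.
#' @return `counts`, invisibly; errors otherwise.
#' @export
validate_count_matrix <- function(counts) {
  if (!is.matrix(counts)) stop("counts must be a matrix", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry gene ids (rownames) and voxel ids (colnames)",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids", call. = FALSE)
  if (anyDuplicated(colnames(counts))) stop("duplicate voxel ids", call. = FALSE)
  if (anyNA(counts)) stop("counts contain missing values", call. = FALSE)
  if (any(counts < 0)) stop("negative count", call. = FALSE)
  if (any(counts != round(counts))) stop("non-integer count", call. = FALSE)
  invisible(counts)
}

#' Read a voxel layout table
#'
#' Reads the CSV mapping each voxel to its position on the regular
#' microdissection grid: columns `voxel_id`, `section_id`, `row`, `col`.
#' Coordinates are 0-based; row increases ventrally (downward in the rendered
#' image) and col laterally (rightward). The listed voxels define the tissue
#' mask — positions absent from the table are background, never imputed.
#'
#' @param path Path to the layout CSV.
#' @param pitch_um Grid pitch in micrometres (voxel edge length); default 50.
#' @return A tibble with columns `voxel_id`, `section_id`, `row`, `col` and a
#'   `pitch_um` attribute.
#' @export
read_voxel_layout <- function(path, pitch_um = 50) {
  grid <- readr::read_csv(path, col_types = readr::cols(
    voxel_id = readr::col_character(),
    section_id = readr::col_character(),
    row = readr::col_double(),
    col = readr::col_double()
  ))
  validate_voxel_layout(grid, pitch_um = pitch_um)
}

#' @rdname read_voxel_layout
#' @param grid A data frame with columns `voxel_id`, `section_id`, `row`, `col`.
#' @export
validate_voxel_layout <- function(grid, pitch_um = 50) {
  needed <- c("voxel_id", "section_id", "row", "col")
  missing_cols <- setdiff(needed, names(grid))
  if (length(missing_cols)) {
    stop("layout missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (pitch_um <= 0) stop("pitch_um must be > 0", call. = FALSE)
  if (any(grid$row != floor(grid$row)) || any(grid$col != floor(grid$col))) {
    stop("non-integer grid coordinates", call. = FALSE)
  }
  if (any(grid$row < 0) || any(grid$col < 0)) {
    stop("grid coordinates must be >= 0", call. = FALSE)
  }
  if (anyDuplicated(grid$voxel_id)) {
    stop("duplicate voxel_id: ", grid$voxel_id[duplicated(grid$voxel_id)][1L],
         call. = FALSE)
  }
  pos <- paste(grid$section_id, grid$row, grid$col, sep = "/")
  if (anyDuplicated(pos)) {
    stop("duplicate grid position: ", pos[duplicated(pos)][1L], call. = FALSE)
  }
  out <- tibble::as_tibble(grid[needed])
  out$row <- as.integer(out$row)
  out$col <- as.integer(out$col)
  attr(out, "pitch_um") <- pitch_um
  out
}

#' Write a voxel layout table
#'
#' @param grid Layout tibble as returned by [read_voxel_layout()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_voxel_layout <- function(grid, path) {
  readr::write_csv(grid[, c("voxel_id", "section_id", "row", "col")], path)
  invisible(path)
}

#' Align a count matrix with a voxel layout
#'
#' Restricts both inputs to their shared voxel ids, reordered identically
#' (count-matrix column order). Voxels present in only one input are dropped
#' with a warning; downstream analysis runs on the intersection only.
#'
#' @param counts Count matrix (genes x voxels).
#' @param grid Voxel layout tibble.
#' @return A list with elements `counts` and `grid` over the shared voxels.
#' @export
align_voxels <- function(counts, grid) {
  validate_count_matrix(counts)
  shared <- intersect(colnames(counts), grid$voxel_id)
  if (length(shared) == 0L) {
    stop("no voxel ids shared between counts and layout", call. = FALSE)
  }
  only_counts <- setdiff(colnames(counts), shared)
  only_grid <- setdiff(grid$voxel_id, shared)
  if (length(only_counts)) {
    warning("dropping ", length(only_counts),
            " voxel(s) present only in counts: ",
            paste(utils::head(only_counts, 5), collapse = ", "),
            if (length(only_counts) > 5) ", ..." else "", call. = FALSE)
  }
  if (length(only_grid)) {
    warning("dropping ", length(only_grid),
            " voxel(s) present only in layout: ",
            paste(utils::head(only_grid, 5), collapse = ", "),
            if (length(only_grid) > 5) ", ..." else "", call. = FALSE)
  }
  keep <- colnames(counts)[colnames(counts) %in% shared]
  grid2 <- grid[match(keep, grid$voxel_id), , drop = FALSE]
  attr(grid2, "pitch_um") <- attr(grid, "pitch_um")
  list(counts = counts[, keep, drop = FALSE], grid = grid2)
}

#' Load a GEO series-matrix export as a count matrix
#'
#' Parses the text format produced by a GEO series-matrix download (the data
#' block between `!series_matrix_table_begin` and `!series_matrix_table_end`,
#' tab-separated, sample ids possibly quoted). A file without the series-matrix
#' markers is treated as a plain processed genes-by-samples table in the
#' package TSV dialect.
#'
#' @param path Path to the downloaded file.
#' @return An integer count matrix, genes x samples.
#' @export
load_geo_series_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  begin <- grep("^!series_matrix_table_begin", lines)
  if (length(begin) == 0L) {
    return(read_count_matrix(path, format = "tsv"))
  }
  end <- grep("^!series_matrix_table_end", lines)
  if (length(end) == 0L || end[1L] <= begin[1L] + 1L) {
    stop("truncated series matrix: no table end marker after line ", begin[1L],
         call. = FALSE)
  }
  block <- lines[(begin[1L] + 1L):(end[1L] - 1L)]
  unquote <- function(x) gsub('^"|"$', "", x)
  header <- unquote(strsplit(block[[1L]], "\t", fixed = TRUE)[[1L]])
  if (length(header) < 2L) {
    stop("unrecognized layout at line ", begin[1L] + 1L, ": '",
         block[[1L]], "'", call. = FALSE)
  }
  sample_ids <- header[-1L]
  body <- block[-1L]
  gene_ids <- character(length(body))
  counts <- matrix(0L, nrow = length(body), ncol = length(sample_ids))
  for (i in seq_along(body)) {
    fields <- unquote(strsplit(body[[i]], "\t", fixed = TRUE)[[1L]])
    if (length(fields) != length(sample_ids) + 1L) {
      stop("unrecognized layout at line ", begin[1L] + 1L + i, ": '",
           body[[i]], "'", call. = FALSE)
    }
    gene_ids[[i]] <- fields[[1L]]
    vals <- suppressWarnings(as.numeric(fields[-1L]))
    if (anyNA(vals) || any(vals < 0) || any(abs(vals - round(vals)) > 1e-6)) {
      stop("unrecognized layout at line ", begin[1L] + 1L + i, ": '",
           body[[i]], "'", call. = FALSE)
    }
    counts[i, ] <- as.integer(round(vals))
  }
  dimnames(counts) <- list(gene_ids, sample_ids)
  validate_count_matrix(counts)
  counts
}
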
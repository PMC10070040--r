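#' Paired single-cell multi-omics container
#'
#' An `omics_pair` holds cell-matched scRNA-seq counts and binarized
#' scATAC accessibility over the same `N` cells: raw RNA counts (the
#' target of the zero-inflated negative binomial likelihood), their
#' normalized counterpart (the encoder input), and the binary peak
#' matrix (both Bernoulli target and encoder input).
#'
#' @param rna_counts non-negative integer matrix, cells x genes.
#' @param atac binary (or binarizable, values > 0 set to 1) matrix,
#'   cells x peaks, rows matched to `rna_counts`.
#' @param cell_ids,gene_ids,peak_ids optional identifier vectors; taken
#'   from dimnames when missing.
#'
#' @return An object of class `omics_pair` with fields `rna_counts`,
#'   `rna_norm`, `atac_bin`, `cell_ids`, `gene_ids`, `peak_ids`.
#' @export
omics_pair <- function(rna_counts, atac, cell_ids = NULL, gene_ids = NULL,
                       peak_ids = NULL) {
  rna_counts <- as.matrix(rna_counts)
  atac <- as.matrix(atac)
  if (nrow(rna_counts) != nrow(atac))
    stop("paired-data error: RNA and ATAC must have the same cells in the same order")
  if (nrow(rna_counts) < 2L) stop("paired-data error: need at least 2 cells")
  check_counts(rna_counts)
  if (any(atac < 0)) stop("format error: negative ATAC entries")
  atac_bin <- (atac > 0) * 1
  cell_ids <- cell_ids %||% rownames(rna_counts) %||% paste0("cell", seq_len(nrow(rna_counts)))
  gene_ids <- gene_ids %||% colnames(rna_counts) %||% paste0("gene", seq_len(ncol(rna_counts)))
  peak_ids <- peak_ids %||% colnames(atac) %||% paste0("peak", seq_len(ncol(atac)))
  dimnames(rna_counts) <- list(cell_ids, gene_ids)
  dimnames(atac_bin) <- list(cell_ids, peak_ids)
  structure(list(rna_counts = rna_counts,
                 rna_norm = normalize_rna(rna_counts),
                 atac_bin = atac_bin,
                 cell_ids = cell_ids, gene_ids = gene_ids, peak_ids = peak_ids),
            class = "omics_pair")
}

#' @export
print.omics_pair <- function(x, ...) {
  cat(sprintf("omics_pair: %d cells, %d genes (RNA), %d peaks (ATAC)\n",
              length(x$cell_ids), length(x$gene_ids), length(x$peak_ids)))
  cat(sprintf("  RNA zero fraction %.3f | ATAC open fraction %.3f\n",
              mean(x$rna_counts == 0), mean(x$atac_bin)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_counts <- function(m) {
  if (any(m < 0) || any(m != floor(m)))
    stop("format error: RNA counts must be non-negative integers")
  invisible(TRUE)
}

#' Normalize an RNA count matrix for the encoder
#'
#' Scales each cell to the median library size across cells, then
#' applies `log(1 + x)`. Cells with zero total counts are left as zeros
#' with a warning.
#'
#' @param rna_counts non-negative integer matrix, cells x genes.
#' @return Real matrix of the same shape.
#' @export
normalize_rna <- function(rna_counts) {
  rna_counts <- as.matrix(rna_counts)
  check_counts(rna_counts)
  lib <- rowSums(rna_counts)
  if (all(lib == 0)) {
    warning("all cells have zero library size; returning zeros")
    return(rna_counts * 0)
  }
  if (any(lib == 0)) warning(sprintf("%d cell(s) with zero library size left as zeros",
                                     sum(lib == 0)))
  med <- stats::median(lib[lib > 0])
  sf <- ifelse(lib > 0, med / lib, 0)
  log1p(rna_counts * sf)
}

#' One-hot omics-label matrix for the discriminator
#'
#' Rows `1..n_cells` mark omics 1 (RNA), rows `n_cells+1..2*n_cells`
#' mark omics 2 (ATAC); matches the row order of the stacked
#' individuality embeddings fed to the omics-label discriminator.
#'
#' @param n_cells number of cells per omics (>= 1).
#' @return A `2*n_cells x 2` binary matrix with one-hot rows.
#' @export
make_omics_labels <- function(n_cells) {
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 1)
    stop("argument error: n_cells must be a positive integer")
  n_cells <- as.integer(n_cells)
  rbind(matrix(rep(c(1, 0), each = n_cells), n_cells, 2),
        matrix(rep(c(0, 1), each = n_cells), n_cells, 2))
}

# ---- readers / writers ------------------------------------------------

# Resolve an MTX triplet: `path` is either a directory containing
# matrix.mtx + features.tsv + barcodes.tsv (10X layout) or the .mtx file
# itself with sidecars in the same directory.
resolve_mtx <- function(path) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    dirn <- path
  } else {
    mtx <- path
    dirn <- dirname(path)
  }
  feat <- file.path(dirn, "features.tsv")
  if (!file.exists(feat)) feat <- file.path(dirn, "genes.tsv")
  bar <- file.path(dirn, "barcodes.tsv")
  for (f in c(mtx, feat, bar)) if (!file.exists(f)) stop("format error: missing file ", f)
  list(mtx = mtx, features = feat, barcodes = bar)
}

# Read one omics layer; returns cells x features base matrix with dimnames.
read_layer <- function(path, format) {
  if (format == "mtx") {
    fs <- resolve_mtx(path)
    m <- as.matrix(Matrix::readMM(fs$mtx))          # features x cells on disk
    feats <- utils::read.delim(fs$features, header = FALSE)[[1]]
    cells <- utils::read.delim(fs$barcodes, header = FALSE)[[1]]
    if (nrow(m) != length(feats) || ncol(m) != length(cells))
      stop("format error: sidecar lengths do not match matrix dimensions")
    m <- t(m)
    dimnames(m) <- list(cells, feats)
    m
  } else if (format == "dense_delim") {
    sep <- if (grepl("\\.csv$", path)) "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                            check.names = FALSE)
    as.matrix(df)
  } else stop("argument error: unknown format '", format, "'")
}

#' Read a paired RNA/ATAC dataset
#'
#' Reads the two layers, intersects barcodes, co-orders both matrices by
#' the RNA barcode order restricted to the intersection, validates RNA
#' counts and binarizes ATAC (any value > 0 becomes 1).
#'
#' @param rna_path,atac_path for `format = "mtx"`: a directory holding
#'   `matrix.mtx`, `features.tsv` (or `genes.tsv`), `barcodes.tsv`
#'   (features x cells on disk, 10X convention), or the `.mtx` file
#'   itself with the sidecars beside it. For `format = "dense_delim"`:
#'   a TSV/CSV with a header row of feature ids and first column of
#'   cell ids (cells x features).
#' @param format `"mtx"` or `"dense_delim"`.
#' @return An [omics_pair].
#' @export
read_omics_pair <- function(rna_path, atac_path, format = c("mtx", "dense_delim")) {
  format <- match.arg(format)
  rna <- read_layer(rna_path, format)
  atac <- read_layer(atac_path, format)
  shared <- intersect(rownames(rna), rownames(atac))
  if (length(shared) == 0L)
    stop("paired-data error: no shared barcodes between RNA and ATAC")
  rna <- rna[shared, , drop = FALSE]
  atac <- atac[shared, , drop = FALSE]
  omics_pair(rna, atac, cell_ids = shared)
}

write_layer <- function(m, path, format) {
  if (format == "mtx") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(Matrix::Matrix(t(m), sparse = TRUE), file.path(path, "matrix.mtx"))
    writeLines(colnames(m), file.path(path, "features.tsv"))
    writeLines(rownames(m), file.path(path, "barcodes.tsv"))
  } else {
    df <- data.frame(cell_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write a paired dataset in the same dialects the reader accepts
#'
#' @param pair an [omics_pair].
#' @param dir output directory; layers go to `rna/` and `atac/`
#'   subdirectories (mtx) or `rna.tsv` / `atac.tsv` (dense).
#' @param format `"mtx"` or `"dense_delim"`.
#' @return `dir`, invisibly.
#' @export
write_omics_pair <- function(pair, dir, format = c("mtx", "dense_delim")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (format == "mtx") {
    write_layer(pair$rna_counts, file.path(dir, "rna"), "mtx")
    write_layer(pair$atac_bin, file.path(dir, "atac"), "mtx")
  } else {
    write_layer(pair$rna_counts, file.path(dir, "rna.tsv"), "dense_delim")
    write_layer(pair$atac_bin, file.path(dir, "atac.tsv"), "dense_delim")
  }
  invisible(dir)
}
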
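#' Paired single-cell multi-omics container
#'
#' Bundles an RNA count matrix and an ATAC accessibility matrix measured in
#' the same cells, in the same row (cell) order, together with cell and
#' feature identifiers and optional ground-truth labels.
#'
#' @param rna_counts numeric matrix, cells x genes, non-negative.
#' @param atac_counts numeric matrix, cells x peaks, non-negative.
#' @param cell_ids character vector of unique cell barcodes (defaults to
#'   rownames of `rna_counts`, or `cell_1..cell_N`).
#' @param rna_feature_ids,atac_feature_ids character vectors matching the
#'   matrix widths.
#' @param labels optional vector of per-cell group labels (length N).
#'
#' @return An object of class `paired_omics`: a list with elements
#'   `rna_counts`, `atac_counts`, `cell_ids`, `rna_feature_ids`,
#'   `atac_feature_ids`, `labels`.
#' @export
paired_omics <- function(rna_counts, atac_counts, cell_ids = NULL,
                         rna_feature_ids = NULL, atac_feature_ids = NULL,
                         labels = NULL) {
  rna_counts <- as.matrix(rna_counts)
  atac_counts <- as.matrix(atac_counts)
  n <- nrow(rna_counts)
  if (nrow(atac_counts) != n)
    stop("rna_counts and atac_counts must have the same number of rows (cells): ",
         n, " vs ", nrow(atac_counts))
  if (n < 2) stop("need at least 2 cells")
  for (m in list(rna_counts, atac_counts)) {
    if (!all(is.finite(m))) stop("matrix entries must be finite")
    if (any(m < 0)) stop("matrix entries must be non-negative")
  }
  if (is.null(cell_ids)) cell_ids <- rownames(rna_counts)
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(n))
  cell_ids <- as.character(cell_ids)
  if (length(cell_ids) != n) stop("cell_ids length must equal the cell count")
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique")
  if (is.null(rna_feature_ids)) rna_feature_ids <- colnames(rna_counts)
  if (is.null(rna_feature_ids))
    rna_feature_ids <- paste0("gene_", seq_len(ncol(rna_counts)))
  if (is.null(atac_feature_ids)) atac_feature_ids <- colnames(atac_counts)
  if (is.null(atac_feature_ids))
    atac_feature_ids <- paste0("peak_", seq_len(ncol(atac_counts)))
  if (length(rna_feature_ids) != ncol(rna_counts))
    stop("rna_feature_ids length must match ncol(rna_counts)")
  if (length(atac_feature_ids) != ncol(atac_counts))
    stop("atac_feature_ids length must match ncol(atac_counts)")
  if (!is.null(labels) && length(labels) != n)
    stop("labels length must equal the cell count")
  dimnames(rna_counts) <- list(cell_ids, as.character(rna_feature_ids))
  dimnames(atac_counts) <- list(cell_ids, as.character(atac_feature_ids))
  structure(list(rna_counts = rna_counts, atac_counts = atac_counts,
                 cell_ids = cell_ids,
                 rna_feature_ids = as.character(rna_feature_ids),
                 atac_feature_ids = as.character(atac_feature_ids),
                 labels = labels),
            class = "paired_omics")
}

#' @export
print.paired_omics <- function(x, ...) {
  cat("paired_omics:", length(x$cell_ids), "cells |",
      length(x$rna_feature_ids), "genes |",
      length(x$atac_feature_ids), "peaks")
  if (!is.null(x$labels))
    cat(" |", length(unique(x$labels)), "label groups")
  cat("\n")
  invisible(x)
}

# read a dense CSV/TSV matrix: header row = feature ids, first column = cell ids
read_dense_matrix <- function(path, sep) {
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(!apply(df, 2, function(col) all(!is.na(suppressWarnings(as.numeric(col))))))
    stop("non-numeric entries in ", path,
         if (length(bad)) paste0(" (first offending column: ", colnames(df)[bad[1]], ")"))
  }
  m
}

# read an MTX matrix with barcodes.tsv / features.tsv companions in the same
# directory; orientation is resolved by matching the barcode count
read_mtx_matrix <- function(path) {
  dir <- dirname(path)
  find_companion <- function(cands) {
    for (f in cands) {
      p <- file.path(dir, f)
      if (file.exists(p)) return(p)
    }
    stop("no companion file (tried: ", paste(cands, collapse = ", "),
         ") next to ", path)
  }
  bc_path <- find_companion(c("barcodes.tsv", "barcodes.txt"))
  ft_path <- find_companion(c("features.tsv", "features.txt", "genes.tsv"))
  barcodes <- utils::read.table(bc_path, sep = "\t",
                                stringsAsFactors = FALSE)[[1]]
  features <- utils::read.table(ft_path, sep = "\t",
                                stringsAsFactors = FALSE)[[1]]
  m <- as.matrix(Matrix::readMM(path))
  if (nrow(m) == length(barcodes) && ncol(m) == length(features)) {
    # already cells x features
  } else if (ncol(m) == length(barcodes) && nrow(m) == length(features)) {
    m <- t(m)
  } else {
    stop("MTX dimensions ", nrow(m), "x", ncol(m),
         " match neither orientation of ", length(barcodes), " barcodes x ",
         length(features), " features")
  }
  dimnames(m) <- list(barcodes, features)
  m
}

#' Load paired RNA/ATAC matrices from disk
#'
#' Reads both modalities, checks that they describe the same cells, and
#' aligns the ATAC matrix to the RNA barcode order. Mismatched cell sets are
#' an error, not an intersection: paired protocols guarantee identical cells,
#' so a mismatch signals a data problem.
#'
#' @param rna_path,atac_path matrix files. For `format = "mtx"` each must
#'   have `barcodes.tsv` and `features.tsv` companions in its directory.
#' @param format one of `"mtx"`, `"csv"`, `"tsv"`. CSV/TSV layout: header row
#'   of feature ids, first column of cell ids.
#' @param labels_path optional text file with one label per line, in the RNA
#'   barcode order.
#' @return A [paired_omics] object.
#' @export
load_paired_matrices <- function(rna_path, atac_path,
                                 format = c("csv", "tsv", "mtx"),
                                 labels_path = NULL) {
  format <- match.arg(format)
  reader <- switch(format,
                   csv = function(p) read_dense_matrix(p, ","),
                   tsv = function(p) read_dense_matrix(p, "\t"),
                   mtx = read_mtx_matrix)
  rna <- reader(rna_path)
  atac <- reader(atac_path)
  rb <- rownames(rna); ab <- rownames(atac)
  if (is.null(rb) || is.null(ab)) stop("cell identifiers missing")
  missing_in_atac <- setdiff(rb, ab)
  missing_in_rna <- setdiff(ab, rb)
  if (length(missing_in_atac) || length(missing_in_rna)) {
    stop("cell sets differ between modalities; first RNA-only barcode: ",
         if (length(missing_in_atac)) missing_in_atac[1] else "<none>",
         "; first ATAC-only barcode: ",
         if (length(missing_in_rna)) missing_in_rna[1] else "<none>")
  }
  atac <- atac[rb, , drop = FALSE]
  labels <- NULL
  if (!is.null(labels_path)) {
    labels <- readLines(labels_path)
    labels <- labels[nzchar(labels)]
    if (length(labels) != nrow(rna))
      stop("labels file has ", length(labels), " entries for ", nrow(rna), " cells")
  }
  paired_omics(rna, atac, cell_ids = rb, labels = labels)
}

#' Write a paired dataset to CSV files
#'
#' Inverse of [load_paired_matrices()] with `format = "csv"`; reloading the
#' written files reproduces the matrices exactly.
#'
#' @param data a [paired_omics] object.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written (`rna`, `atac`, and `labels` if
#'   labels are present).
#' @export
write_paired_csv <- function(data, dir) {
  stopifnot(inherits(data, "paired_omics"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_one <- function(m, path) {
    df <- data.frame(cell_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  }
  paths <- list(rna = file.path(dir, "rna.csv"),
                atac = file.path(dir, "atac.csv"))
  write_one(data$rna_counts, paths$rna)
  write_one(data$atac_counts, paths$atac)
  if (!is.null(data$labels)) {
    paths$labels <- file.path(dir, "labels.txt")
    writeLines(as.character(data$labels), paths$labels)
  }
  invisible(paths)
}

#' Library-size normalisation for RNA counts
#'
#' Scales each cell's counts to the median library size across cells, then
#' applies `log1p`. All-zero cells pass through unchanged. The result is what
#' the RNA encoder consumes; the zero-inflated negative binomial
#' reconstruction loss is evaluated on the raw counts, which should be kept
#' separately.
#'
#' @param counts non-negative matrix, cells x genes.
#' @return matrix of the same shape, finite and non-negative.
#' @export
normalize_rna <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  lib <- rowSums(counts)
  med <- stats::median(lib[lib > 0])
  if (!is.finite(med) || med == 0) return(counts * 0)
  scale <- ifelse(lib > 0, med / lib, 0)
  log1p(counts * scale)
}

#' Binarize ATAC accessibility
#'
#' Maps every positive entry to 1 and zeros to 0, the form the Bernoulli
#' likelihood requires. Idempotent.
#'
#' @param counts non-negative matrix, cells x peaks.
#' @return binary matrix of the same shape.
#' @export
binarize_atac <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  (counts > 0) * 1
}

#' Keep the most variable features
#'
#' Retains the `n_top` columns with the highest variance across cells, ties
#' broken towards the lower column index. Column order of the kept features
#' is preserved.
#'
#' @param m matrix, cells x features.
#' @param n_top number of columns to keep (`<= ncol(m)`).
#' @return list with `matrix` (cells x `n_top`) and `indices` (ascending
#'   1-based column indices of the kept features).
#' @export
select_features <- function(m, n_top) {
  m <- as.matrix(m)
  if (n_top > ncol(m)) stop("n_top (", n_top, ") exceeds feature count (", ncol(m), ")")
  if (n_top < 1) stop("n_top must be positive")
  v <- apply(m, 2, stats::var)
  # order(-v) is stable: ties resolve to the lower column index
  keep <- sort(order(-v)[seq_len(n_top)])
  list(matrix = m[, keep, drop = FALSE], indices = keep)
}
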
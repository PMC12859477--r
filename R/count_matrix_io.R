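#' Build a cell x guide UMI count matrix
#'
#' The canonical in-memory container is a sparse `dgCMatrix` with cell
#' barcodes as rownames and guide ids as colnames; entries are nonnegative
#' integer UMI counts.
#'
#' @param counts Matrix-like of nonnegative integers (dense or sparse).
#' @param barcodes Character rownames (cells); unique.
#' @param guide_ids Character colnames (guides); unique.
#' @return A `dgCMatrix` with dimnames set.
#' @export
guide_count_matrix <- function(counts, barcodes = rownames(counts),
                               guide_ids = colnames(counts)) {
  m <- methods::as(methods::as(methods::as(
    Matrix::Matrix(counts, sparse = TRUE), "dMatrix"),
    "generalMatrix"), "CsparseMatrix")
  if (length(m@x) && (any(m@x < 0) || any(m@x != round(m@x))))
    stop("count matrix entries must be nonnegative integers")
  if (is.null(barcodes) || is.null(guide_ids))
    stop("count matrix needs cell barcodes and guide ids")
  if (anyDuplicated(barcodes)) stop("duplicate cell barcode in matrix axis")
  if (anyDuplicated(guide_ids)) stop("duplicate guide id in matrix axis")
  dimnames(m) <- list(as.character(barcodes), as.character(guide_ids))
  m
}

#' Write a count matrix as a MatrixMarket triplet directory
#'
#' Emits the standard trio `matrix.mtx` (coordinate integer general, 1-based
#' indices), `barcodes.tsv` (cell axis) and `features.tsv` (guide axis),
#' the layout used by droplet single-cell pipelines. Output is
#' deterministic: identical matrices give byte-identical files.
#'
#' @param m Cell x guide count matrix (see [guide_count_matrix()]).
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_count_matrix <- function(m, dir) {
  # a 0-row/0-col axis legitimately has no names
  if ((nrow(m) > 0 && is.null(rownames(m))) ||
      (ncol(m) > 0 && is.null(colnames(m))))
    stop("count matrix must carry barcode rownames and guide colnames")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # genes-as-rows on disk (10x convention); cells-as-rows in memory
  Matrix::writeMM(Matrix::t(m), file.path(dir, "matrix.mtx"))
  writeLines(as.character(rownames(m)), file.path(dir, "barcodes.tsv"))
  writeLines(as.character(colnames(m)), file.path(dir, "features.tsv"))
  invisible(dir)
}

#' Read a MatrixMarket triplet directory back into a count matrix
#'
#' @param dir Directory containing `matrix.mtx`, `barcodes.tsv`,
#'   `features.tsv`. A missing companion file is a hard error.
#' @return A cell x guide `dgCMatrix`; `read(write(m))` equals `m`.
#' @export
read_count_matrix <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "barcodes.tsv", "features.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0)
    stop("count matrix directory is missing: ",
         paste(basename(missing), collapse = ", "))
  m <- Matrix::t(Matrix::readMM(paths[1]))
  barcodes <- readLines(paths[2])
  features <- readLines(paths[3])
  if (nrow(m) != length(barcodes) || ncol(m) != length(features))
    stop("matrix dimensions disagree with barcodes/features files")
  guide_count_matrix(m, barcodes, features)
}

# Locale-independent lexicographic order (radix = byte order).
c_order <- function(...) order(..., method = "radix")

#' Write per-(cell, guide) calls to a tab-delimited file
#'
#' Rows are sorted by cell barcode then guide id (byte order) so identical
#' call sets always produce byte-identical files; posteriors are printed
#' with 8 significant digits (`NA` for guides called through the
#' degenerate-count fallback).
#'
#' @param calls Data frame with columns `cell_barcode`, `guide_id`, `count`,
#'   `posterior`, `expressed` (see [classify_counts()]).
#' @param path Output TSV path.
#' @export
write_calls <- function(calls, path) {
  need <- c("cell_barcode", "guide_id", "count", "posterior", "expressed")
  stopifnot(all(need %in% names(calls)))
  calls <- calls[c_order(calls$cell_barcode, calls$guide_id), need]
  calls$posterior <- ifelse(is.na(calls$posterior), "NA",
                            sprintf("%.8g", calls$posterior))
  calls$expressed <- ifelse(calls$expressed, "TRUE", "FALSE")
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Write per-cell assignments to a tab-delimited file
#'
#' @param assignments Data frame from [assign_cells()].
#' @param path Output TSV path.
#' @export
write_assignments <- function(assignments, path) {
  need <- c("cell_barcode", "called_guides", "n_called", "category",
            "target", "retained_for_analysis")
  stopifnot(all(need %in% names(assignments)))
  a <- assignments[c_order(assignments$cell_barcode), need]
  a$target <- ifelse(is.na(a$target), "NA", a$target)
  utils::write.table(a, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}
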
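#' Construct a cell-barcode list
#'
#' Holds the set of canonical cell barcodes (e.g. the cells called by the
#' upstream multiome pipeline) plus an optional translation map from the
#' barcode as captured in the guide library to the canonical barcode. The
#' translation exists because droplet multiome gel beads carry distinct
#' ATAC-side and GEX-side barcode sequences; when no translation is given,
#' captured barcodes are matched against the canonical list as-is.
#'
#' @param barcodes Character vector of equal-length DNA barcodes.
#' @param translation Optional named character vector: names are captured
#'   barcodes, values are canonical barcodes drawn from `barcodes`.
#' @return A `barcode_list` object.
#' @export
barcode_list <- function(barcodes, translation = NULL) {
  barcodes <- as.character(barcodes)
  if (length(barcodes) == 0) stop("empty barcode list")
  len <- unique(nchar(barcodes))
  if (length(len) != 1)
    stop("mixed barcode lengths in barcode list: ",
         paste(sort(len), collapse = ", "))
  if (anyDuplicated(barcodes))
    stop("duplicate barcode in list: ", barcodes[duplicated(barcodes)][1])
  if (!is.null(translation)) {
    if (is.null(names(translation)) || anyDuplicated(names(translation)))
      stop("translation keys must be unique and named")
    if (!all(translation %in% barcodes))
      stop("translation values must be drawn from the canonical barcode list")
    if (length(unique(nchar(names(translation)))) != 1)
      stop("mixed captured-barcode lengths in translation table")
  }
  structure(list(barcodes = barcodes, translation = translation,
                 bc_length = len),
            class = "barcode_list")
}

#' Read a cell-barcode list (and optional translation table) from disk
#'
#' @param path One barcode per line, optionally gzipped (a `barcodes.tsv` or
#'   `barcodes.tsv.gz` as emitted by droplet pipelines). A trailing `-1`
#'   style suffix is kept verbatim if present.
#' @param translation_path Optional two-column TSV (captured barcode,
#'   canonical barcode), no header.
#' @return A [barcode_list()]. Translation is applied lazily at lookup time
#'   via [lookup_barcode()].
#' @export
read_barcode_list <- function(path, translation_path = NULL) {
  if (!file.exists(path)) stop("barcode list file not found: ", path)
  bcs <- readLines(path)
  bcs <- bcs[nzchar(bcs)]
  translation <- NULL
  if (!is.null(translation_path)) {
    if (!file.exists(translation_path))
      stop("translation file not found: ", translation_path)
    tr <- utils::read.delim(translation_path, header = FALSE, sep = "\t",
                            colClasses = "character")
    if (ncol(tr) != 2) stop("translation file must have two columns")
    translation <- stats::setNames(tr[[2]], tr[[1]])
  }
  barcode_list(bcs, translation)
}

#' Look up (and translate) a captured barcode
#'
#' @param bl A [barcode_list()].
#' @param bc Character vector of captured barcodes.
#' @return The canonical barcode for each `bc`: translated when a
#'   translation map is present, otherwise `bc` itself; `NA` when a
#'   translation map exists but does not cover `bc`.
#' @export
lookup_barcode <- function(bl, bc) {
  stopifnot(inherits(bl, "barcode_list"))
  if (is.null(bl$translation)) return(bc)
  unname(bl$translation[bc])
}

# The whitelist in *captured* space: translation keys when present,
# otherwise the canonical barcodes themselves.
captured_whitelist <- function(bl) {
  if (is.null(bl$translation)) bl$barcodes else names(bl$translation)
}

#' @export
print.barcode_list <- function(x, ...) {
  cat("Barcode list:", length(x$barcodes), "barcodes of length",
      x$bc_length,
      if (is.null(x$translation)) "(no translation)" else
        sprintf("(%d translated)", length(x$translation)), "\n")
  invisible(x)
}
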
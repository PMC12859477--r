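#' Construct and validate a guide library
#'
#' A guide library describes the CRISPR constructs used in a screen: one row
#' per guide, with its protospacer sequence, the gene it targets (or a
#' non-targeting label) and the vector it is expressed from. The dual-guide
#' design groups at most two protospacers per vector, both targeting the
#' same gene.
#'
#' @param df A data.frame with character columns `guide_id`, `protospacer`,
#'   `target`, `vector_id`.
#' @return A `guide_library`, a validated data.frame with uppercase
#'   protospacers.
#' @examples
#' lib <- guide_library(data.frame(
#'   guide_id = c("GATA5_PS1", "GATA5_PS2"),
#'   protospacer = c("GAGCCTGGACTCCCTGGAGT", "GCCCAGGACAGGGAGGGAGC"),
#'   target = "GATA5", vector_id = "V_GATA5"))
#' @export
guide_library <- function(df) {
  required <- c("guide_id", "protospacer", "target", "vector_id")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("guide library is missing column(s): ", paste(missing, collapse = ", "))
  df <- as.data.frame(df)[required]
  for (col in required) {
    df[[col]] <- as.character(df[[col]])
    if (any(is.na(df[[col]]) | df[[col]] == ""))
      stop("guide library has empty values in column '", col, "' (row ",
           which(is.na(df[[col]]) | df[[col]] == "")[1], ")")
  }
  df$protospacer <- toupper(df$protospacer)

  dup <- df$guide_id[duplicated(df$guide_id)]
  if (length(dup) > 0)
    stop("duplicate guide_id in guide library: ", dup[1])
  dup <- df$protospacer[duplicated(df$protospacer)]
  if (length(dup) > 0)
    stop("duplicate protospacer in guide library: ", dup[1])

  bad <- grepl("[^ACGT]", df$protospacer)
  if (any(bad))
    stop("protospacer with non-ACGT character at line ", which(bad)[1] + 1L,
         " (guide ", df$guide_id[which(bad)[1]], ")")
  len <- nchar(df$protospacer)
  if (any(len < 18L | len > 21L))
    stop("protospacer length outside 18-21 nt at line ",
         which(len < 18L | len > 21L)[1] + 1L)

  per_vec <- table(df$vector_id)
  if (any(per_vec > 2))
    stop("vector_id '", names(per_vec)[which(per_vec > 2)[1]],
         "' groups more than 2 guides (dual-guide design)")

  class(df) <- c("guide_library", "data.frame")
  df
}

#' Read a guide library from a tab-delimited file
#'
#' @param path Path to a TSV with header columns `guide_id`, `protospacer`,
#'   `target`, `vector_id`. Protospacers are case-normalised to uppercase.
#' @return A [guide_library()].
#' @export
read_guide_library <- function(path) {
  if (!file.exists(path)) stop("guide library file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                          colClasses = "character", comment.char = "")
  guide_library(df)
}

#' Write a guide library to a tab-delimited file
#' @param lib A [guide_library()].
#' @param path Output path.
#' @export
write_guide_library <- function(lib, path) {
  stopifnot(inherits(lib, "guide_library"))
  utils::write.table(lib, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.guide_library <- function(x, ...) {
  cat("Guide library:", nrow(x), "guides,",
      length(unique(x$vector_id)), "vectors,",
      length(unique(x$target)), "target labels\n")
  print.data.frame(utils::head(x, 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
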
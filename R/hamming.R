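#' Leftmost approximate occurrence of a pattern in a read
#'
#' Slides `pattern` along `read` and reports the leftmost alignment whose
#' Hamming distance (substitutions only, no indels) is at most `d_max`.
#' Ambiguity characters such as `N` never match and therefore count as
#' mismatches.
#'
#' @param read DNA string searched (a single character scalar).
#' @param pattern DNA string over ACGT; if longer than `read` the result is
#'   "no hit" rather than an error.
#' @param d_max Maximum tolerated mismatches (>= 0).
#' @return `NULL` when no alignment qualifies; otherwise a list with
#'   `position` (1-based start of the leftmost qualifying alignment) and
#'   `mismatches` (its Hamming distance).
#' @examples
#' hamming_find("AAGCTTTAAGGCCGGTCCTAGCAATT", cs1_anchor(), 1)
#' @export
hamming_find <- function(read, pattern, d_max = 1L) {
  stopifnot(length(read) == 1, length(pattern) == 1, d_max >= 0)
  if (nchar(pattern) > nchar(read)) return(NULL)
  subject <- Biostrings::DNAString(read)
  hits <- Biostrings::matchPattern(pattern, subject,
                                   max.mismatch = d_max,
                                   with.indels = FALSE, fixed = TRUE)
  if (length(hits) == 0) return(NULL)
  pos <- Biostrings::start(hits)[1]
  mm <- Biostrings::neditStartingAt(Biostrings::DNAString(pattern), subject,
                                    starting.at = pos, fixed = TRUE)
  list(position = pos, mismatches = as.integer(mm))
}

#' Correct a captured cell barcode against a whitelist
#'
#' A barcode already on the whitelist is returned unchanged; otherwise, if
#' exactly one whitelist barcode lies at Hamming distance 1, the read is
#' rescued to that barcode; ambiguous (two or more candidates) or distant
#' barcodes are dropped.
#'
#' @param bc Captured barcode (length must equal the whitelist length).
#' @param bl A [barcode_list()] (matched in captured space when a
#'   translation table is present).
#' @return The corrected captured barcode, or `NA_character_`.
#' @export
correct_barcode <- function(bc, bl) {
  stopifnot(inherits(bl, "barcode_list"))
  correct_barcodes(bc, captured_whitelist(bl))[1]
}

# Vectorised whitelist correction on captured barcodes.
# Exact members pass through; others are rescued iff exactly one whitelist
# barcode is at Hamming distance 1. Returns NA for unrescuable barcodes.
correct_barcodes <- function(bcs, whitelist) {
  out <- ifelse(bcs %in% whitelist, bcs, NA_character_)
  todo <- unique(bcs[is.na(out) & !is.na(bcs)])
  todo <- todo[nchar(todo) == nchar(whitelist[1])]
  if (length(todo) > 0) {
    fixed <- vapply(todo, function(b) {
      nb <- hamming1_neighbors(b)
      hit <- unique(nb[nb %in% whitelist])
      if (length(hit) == 1) hit else NA_character_
    }, character(1))
    idx <- match(bcs, todo)
    take <- !is.na(idx) & is.na(out)
    out[take] <- fixed[idx[take]]
  }
  out
}

# All strings at Hamming distance exactly 1 over {A,C,G,T}.
hamming1_neighbors <- function(s) {
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  unlist(lapply(seq_along(chars), function(i) {
    alt <- bases[bases != chars[i]]
    vapply(alt, function(b) {
      x <- chars; x[i] <- b; paste(x, collapse = "")
    }, character(1))
  }), use.names = FALSE)
}
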
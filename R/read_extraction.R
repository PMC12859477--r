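#' The constant capture-sequence anchor (CS1)
#'
#' Direct-capture guide constructs carry a constant capture sequence 1
#' appended to the gRNA scaffold; the reverse-transcription primer primes on
#' it, so every informative guide read contains it. It is the default
#' anchor for read matching.
#' @return The CS1 DNA string.
#' @export
cs1_anchor <- function() "GCTTTAAGGCCGGTCCTAGCAA"

#' Describe where the barcode, UMI and protospacer live in the reads
#'
#' A guide-capture library is sequenced as one to three synchronized FASTQ
#' streams; the layout says which stream (1-based index into the file list)
#' carries each element, at which offset (bases skipped before the
#' element). The protospacer stream is *searched* (sliding Hamming match)
#' rather than sliced, since the protospacer position varies with the
#' construct.
#'
#' @param bc_stream,bc_offset,bc_len Cell barcode location; default 16 bp at
#'   offset 0 of stream 1 (index reads longer than 16 cycles are simply not
#'   read past the barcode).
#' @param umi_stream,umi_offset,umi_len UMI location; default 12 bp at
#'   offset 0 of stream 2, matching the 12-nt UMI on the capture RT primer.
#' @param ps_stream Stream searched for protospacer and anchor (default 2).
#' @param anchor Constant capture sequence that must co-occur with the
#'   protospacer (default [cs1_anchor()]).
#' @param d_max Maximum Hamming mismatches for both protospacer and anchor
#'   matching (default 1).
#' @param bc_rc Reverse-complement the barcode slice before whitelist
#'   matching (default `FALSE`).
#' @return A `read_layout` object.
#' @export
read_layout <- function(bc_stream = 1L, bc_offset = 0L, bc_len = 16L,
                        umi_stream = 2L, umi_offset = 0L, umi_len = 12L,
                        ps_stream = 2L, anchor = cs1_anchor(),
                        d_max = 1L, bc_rc = FALSE) {
  stopifnot(bc_len > 0, umi_len > 0, d_max >= 0,
            bc_offset >= 0, umi_offset >= 0)
  if (grepl("[^ACGT]", anchor)) stop("anchor must be over {A,C,G,T}")
  structure(list(bc_stream = as.integer(bc_stream),
                 bc_offset = as.integer(bc_offset),
                 bc_len = as.integer(bc_len),
                 umi_stream = as.integer(umi_stream),
                 umi_offset = as.integer(umi_offset),
                 umi_len = as.integer(umi_len),
                 ps_stream = as.integer(ps_stream),
                 anchor = anchor, d_max = as.integer(d_max),
                 bc_rc = isTRUE(bc_rc)),
            class = "read_layout")
}

# Per-read best-mismatch protospacer assignment over the whole library.
# Returns, per read, the 1-based guide index with the fewest mismatches
# (NA when no guide matches within d_max, or the minimum is tied), the
# winning mismatch count, and whether the anchor was found.
match_protospacers <- function(ps_reads, lib, anchor, d_max) {
  n <- length(ps_reads)
  subj <- Biostrings::DNAStringSet(ps_reads)
  anchor_ok <- Biostrings::vcountPattern(anchor, subj, max.mismatch = d_max,
                                         fixed = TRUE) > 0
  best_mm <- rep(Inf, n)
  best_guide <- rep(NA_integer_, n)
  tied <- rep(FALSE, n)
  for (g in seq_len(nrow(lib))) {
    found <- rep(FALSE, n)
    for (d in 0:d_max) {
      cnt <- Biostrings::vcountPattern(lib$protospacer[g], subj,
                                       max.mismatch = d, fixed = TRUE)
      hit <- !found & cnt > 0
      if (any(hit)) {
        better <- hit & d < best_mm
        equal <- hit & d == best_mm
        best_mm[better] <- d
        best_guide[better] <- g
        tied[better] <- FALSE
        tied[equal] <- TRUE
        found <- found | hit
      }
    }
  }
  best_guide[tied] <- NA_integer_
  list(guide = best_guide, mismatches = best_mm,
       anchor_ok = anchor_ok, tied = tied)
}

#' Match one read (set) against the guide library
#'
#' A read yields a UMI record iff some library protospacer occurs in the
#' protospacer stream within `d_max` mismatches *and* the constant anchor
#' occurs within `d_max` mismatches. When several protospacers match, the
#' one with the fewest mismatches wins; an exact tie discards the read.
#'
#' @param streams Character vector: the read from each FASTQ stream.
#' @param layout A [read_layout()].
#' @param lib A [guide_library()].
#' @return A list `(cell_barcode, guide_id, umi)` or `NULL` when the read
#'   is uninformative.
#' @export
match_read <- function(streams, layout, lib) {
  rec <- extract_records_from_streams(as.list(streams), layout, lib)
  if (nrow(rec$records) == 0) return(NULL)
  as.list(rec$records[1, c("cell_barcode", "guide_id", "umi")])
}

# Core vectorised matcher over parallel character vectors of reads.
# Returns records (raw captured barcodes, not yet whitelist-corrected)
# plus a drop tally.
extract_records_from_streams <- function(streams, layout, lib) {
  n <- length(streams[[layout$ps_stream]])
  need_stream <- max(layout$bc_stream, layout$umi_stream, layout$ps_stream)
  if (length(streams) < need_stream)
    stop("layout references stream ", need_stream, " but only ",
         length(streams), " provided")
  bc_reads <- streams[[layout$bc_stream]]
  umi_reads <- streams[[layout$umi_stream]]
  too_short <- nchar(bc_reads) < layout$bc_offset + layout$bc_len |
    nchar(umi_reads) < layout$umi_offset + layout$umi_len
  mm <- match_protospacers(streams[[layout$ps_stream]], lib,
                           layout$anchor, layout$d_max)
  keep <- !too_short & mm$anchor_ok & !is.na(mm$guide)
  drops <- c(
    too_short = sum(too_short),
    no_anchor = sum(!too_short & !mm$anchor_ok),
    no_protospacer = sum(!too_short & mm$anchor_ok & is.na(mm$guide) & !mm$tied),
    ambiguous_protospacer = sum(!too_short & mm$anchor_ok & mm$tied)
  )
  bc <- substr(bc_reads[keep], layout$bc_offset + 1L,
               layout$bc_offset + layout$bc_len)
  if (layout$bc_rc && length(bc) > 0)
    bc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(bc)))
  umi <- substr(umi_reads[keep], layout$umi_offset + 1L,
                layout$umi_offset + layout$umi_len)
  list(records = data.frame(cell_barcode = bc,
                            guide_id = lib$guide_id[mm$guide[keep]],
                            umi = umi, stringsAsFactors = FALSE),
       n_total = n, drops = drops)
}

#' Extract UMI records from guide-capture FASTQ files
#'
#' Reads synchronized (same read order) FASTQ streams and applies
#' [match_read()] logic to every read.
#'
#' @param fastq_paths Character vector of FASTQ paths (plain or gzipped),
#'   in stream order.
#' @param layout A [read_layout()].
#' @param lib A [guide_library()].
#' @return List with `records` (data.frame: `cell_barcode`, `guide_id`,
#'   `umi`), `n_total`, and a named `drops` tally.
#' @export
extract_guide_reads <- function(fastq_paths, layout, lib) {
  streams <- lapply(fastq_paths, function(p) {
    if (!file.exists(p)) stop("FASTQ file not found: ", p)
    as.character(Biostrings::readDNAStringSet(p, format = "fastq"))
  })
  lens <- vapply(streams, length, integer(1))
  if (length(unique(lens)) > 1)
    stop("FASTQ streams are not synchronized: read counts ",
         paste(lens, collapse = ", "))
  extract_records_from_streams(streams, layout, lib)
}

# Directional UMI collapse within one (cell, guide) group: UMIs within
# Hamming distance 1 are absorbed into the higher-read-count UMI (ties:
# the lexicographically smaller absorbs). Returns the number of clusters.
collapse_umis_directional <- function(umis, reads_per_umi) {
  k <- length(umis)
  if (k <= 1) return(k)
  ord <- order(-reads_per_umi, umis, method = "radix")
  umis <- umis[ord]
  mat <- do.call(rbind, strsplit(umis, "", fixed = TRUE))
  claimed <- rep(FALSE, k)
  n_clusters <- 0L
  for (i in seq_len(k)) {
    if (claimed[i]) next
    n_clusters <- n_clusters + 1L
    claimed[i] <- TRUE
    open <- which(!claimed)
    if (length(open) > 0) {
      d <- colSums(t(mat[open, , drop = FALSE]) != mat[i, ])
      claimed[open[d <= 1]] <- TRUE
    }
  }
  n_clusters
}

#' Collapse UMI records into a cell x guide count matrix
#'
#' Captured barcodes are corrected against the whitelist (exact, else a
#' unique Hamming-1 rescue), translated to canonical barcodes when a
#' translation table is present, and UMIs are deduplicated per (cell,
#' guide): `exact` counts distinct UMI strings; `directional` additionally
#' merges UMIs within Hamming distance 1 into the higher-count UMI to
#' absorb sequencing errors.
#'
#' @param records Data frame of UMI records (from [extract_guide_reads()]).
#' @param cells A [barcode_list()]; matrix rows are exactly its canonical
#'   barcodes, in order.
#' @param lib A [guide_library()]; matrix columns are its guides, in order.
#' @param umi_collapse `"exact"` (default) or `"directional"`.
#' @param n_total,drops Optional totals carried from extraction for the
#'   report.
#' @return List with `matrix` (cells x guides `dgCMatrix`) and `report`
#'   (totals: reads in, matched, barcode-corrected, dropped by reason).
#' @export
count_guides <- function(records, cells, lib,
                         umi_collapse = c("exact", "directional"),
                         n_total = nrow(records), drops = c()) {
  umi_collapse <- match.arg(umi_collapse)
  stopifnot(inherits(cells, "barcode_list"), inherits(lib, "guide_library"))
  wl <- captured_whitelist(cells)
  empty <- nrow(records) == 0
  if (!empty && any(!records$guide_id %in% lib$guide_id))
    stop("record with guide_id absent from library")

  corrected <- if (empty) character(0) else
    correct_barcodes(records$cell_barcode, wl)
  n_corrected <- if (empty) 0L else
    sum(!is.na(corrected) & corrected != records$cell_barcode)
  ok <- !is.na(corrected)
  canon <- lookup_barcode(cells, corrected[ok])
  rec <- data.frame(cell = canon,
                    guide = if (empty) character(0) else records$guide_id[ok],
                    umi = if (empty) character(0) else records$umi[ok],
                    stringsAsFactors = FALSE)

  if (nrow(rec) > 0) {
    key <- paste(rec$cell, rec$guide, sep = "\r")
    if (umi_collapse == "exact") {
      dedup <- !duplicated(paste(key, rec$umi, sep = "\r"))
      tab <- table(key[dedup])
    } else {
      reads <- table(paste(key, rec$umi, sep = "\r"))
      parts <- strsplit(names(reads), "\r", fixed = TRUE)
      grp_key <- vapply(parts, function(p) paste(p[1], p[2], sep = "\r"),
                        character(1))
      umi <- vapply(parts, `[`, character(1), 3)
      counts <- vapply(split(seq_along(umi), grp_key), function(ix) {
        collapse_umis_directional(umi[ix], as.vector(reads)[ix])
      }, integer(1))
      tab <- counts
    }
    kk <- strsplit(names(tab), "\r", fixed = TRUE)
    i <- match(vapply(kk, `[`, character(1), 1), cells$barcodes)
    j <- match(vapply(kk, `[`, character(1), 2), lib$guide_id)
    m <- Matrix::sparseMatrix(i = i, j = j, x = as.numeric(tab),
                              dims = c(length(cells$barcodes), nrow(lib)))
  } else {
    m <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(length(cells$barcodes), nrow(lib)))
  }
  m <- guide_count_matrix(m, cells$barcodes, lib$guide_id)
  report <- list(
    n_total_reads = as.integer(n_total),
    n_matched_reads = nrow(records),
    n_barcode_corrected = as.integer(n_corrected),
    n_barcode_unmatched = as.integer(if (empty) 0L else sum(!ok)),
    n_counted_reads = nrow(rec),
    total_umis = as.integer(sum(m)),
    drops = as.list(drops),
    umi_collapse = umi_collapse
  )
  list(matrix = m, report = report)
}

#' One-call extraction pipeline: FASTQ files to count matrix
#'
#' @inheritParams extract_guide_reads
#' @inheritParams count_guides
#' @param cells A [barcode_list()].
#' @return As [count_guides()].
#' @export
count_fastq <- function(fastq_paths, layout, lib, cells,
                        umi_collapse = c("exact", "directional")) {
  ex <- extract_guide_reads(fastq_paths, layout, lib)
  count_guides(ex$records, cells, lib, umi_collapse,
               n_total = ex$n_total, drops = ex$drops)
}
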
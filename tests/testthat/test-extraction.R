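# Read matching, UMI deduplication and counting.

make_streams <- function(bc, umi, insert) {
  # stream 1: barcode read; stream 2: UMI + spacer + insert
  list(paste0(bc, "AGCTAGCT"), paste0(umi, "ACGTACGTAC", insert))
}

test_that("a read needs both protospacer and anchor to yield a record", {
  lib <- toy_library()
  layout <- read_layout()
  bc <- "AAAACCCCGGGGTTTT"
  umi <- "AACCGGTTAACC"
  ok <- make_streams(bc, umi, paste0(lib$protospacer[1], cs1_anchor()))
  rec <- match_read(c(ok[[1]], ok[[2]]), layout, lib)
  expect_equal(rec$guide_id, "GATA5_PS1")
  expect_equal(rec$cell_barcode, bc)
  expect_equal(rec$umi, umi)

  # destroyed anchor (3 substitutions) -> no record despite the protospacer
  bad_anchor <- sub("GCTTT", "CAGTT", cs1_anchor())
  no <- make_streams(bc, umi, paste0(lib$protospacer[1], bad_anchor))
  expect_null(match_read(c(no[[1]], no[[2]]), layout, lib))

  # protospacer alone destroyed -> no record
  no2 <- make_streams(bc, umi, paste0(strrep("A", 20), cs1_anchor()))
  expect_null(match_read(c(no2[[1]], no2[[2]]), layout, lib))
})

test_that("among multiple matching protospacers the fewest mismatches wins", {
  lib <- toy_library()
  layout <- read_layout()
  # mutate GATA5_PS1 by one base: matches PS1 at d=1; also embed exact PS2
  ps1_mut <- sub("^G", "A", lib$protospacer[1])
  insert <- paste0(ps1_mut, "TT", lib$protospacer[2], cs1_anchor())
  st <- make_streams("AAAACCCCGGGGTTTT", "AACCGGTTAACC", insert)
  rec <- match_read(c(st[[1]], st[[2]]), layout, lib)
  # exact (0-mismatch) PS2 beats 1-mismatch PS1
  expect_equal(rec$guide_id, "GATA5_PS2")

  # enumeration oracle: per guide, best mismatch count by brute force
  best_by_brute <- vapply(lib$protospacer, function(p) {
    hit <- hamming_find(st[[2]], p, 1)
    if (is.null(hit)) NA_real_ else hit$mismatches
  }, numeric(1))
  expect_equal(unname(which(best_by_brute == 0)), 2)
})

test_that("an exact tie between two protospacers discards the read", {
  lib <- toy_library()
  layout <- read_layout()
  insert <- paste0(lib$protospacer[1], "TT", lib$protospacer[2],
                   cs1_anchor())
  st <- make_streams("AAAACCCCGGGGTTTT", "AACCGGTTAACC", insert)
  expect_null(match_read(c(st[[1]], st[[2]]), layout, lib))
})

test_that("UMI deduplication: exact keeps distinct strings, directional merges", {
  lib <- toy_library()
  cells <- barcode_list("AAAACCCCGGGGTTTT")
  umi_a <- strrep("A", 12)
  umi_b <- paste0(strrep("A", 11), "C")  # Hamming 1 from umi_a
  rec <- data.frame(
    cell_barcode = "AAAACCCCGGGGTTTT",
    guide_id = "GATA5_PS1",
    umi = c(umi_a, umi_a, umi_a, umi_b),
    stringsAsFactors = FALSE)
  exact <- count_guides(rec, cells, lib, "exact")
  expect_equal(as.numeric(exact$matrix[1, "GATA5_PS1"]), 2)
  dir <- count_guides(rec, cells, lib, "directional")
  expect_equal(as.numeric(dir$matrix[1, "GATA5_PS1"]), 1)
  # two records identical in (bc, guide, umi) -> a single molecule
  rec2 <- rec[c(1, 2), ]
  expect_equal(as.numeric(count_guides(rec2, cells, lib,
                                       "exact")$matrix[1, 1]), 1)
})

test_that("directional collapse matches a brute-force graph oracle", {
  # independent oracle: repeatedly take the (count, -lexicographic) maximal
  # unclaimed UMI as a cluster seed and claim all unclaimed UMIs at d <= 1
  oracle <- function(umis, counts) {
    claimed <- rep(FALSE, length(umis))
    clusters <- 0
    dist1 <- function(a, b)
      sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]) <= 1
    while (any(!claimed)) {
      open <- which(!claimed)
      seed <- open[order(-counts[open], umis[open])[1]]
      claimed[seed] <- TRUE
      for (j in which(!claimed))
        if (dist1(umis[seed], umis[j])) claimed[j] <- TRUE
      clusters <- clusters + 1
    }
    clusters
  }
  lib <- toy_library()
  cells <- barcode_list("AAAACCCCGGGGTTTT")
  set.seed(5)
  for (i in 1:15) {
    k <- sample(2:12, 1)
    umis <- unique(vapply(seq_len(k), function(.)
      paste(sample(c("A", "C"), 6, replace = TRUE), collapse = ""),
      character(1)))  # short alphabet forces collisions/neighbors
    counts <- sample(1:4, length(umis), replace = TRUE)
    rec <- data.frame(
      cell_barcode = "AAAACCCCGGGGTTTT", guide_id = "GATA5_PS1",
      umi = rep(umis, counts), stringsAsFactors = FALSE)
    got <- guidecall:::collapse_umis_directional(umis, counts)
    expect_equal(got, oracle(umis, counts))
  }
})

test_that("empty input produces an all-zero matrix and zeroed report", {
  lib <- toy_library()
  cells <- barcode_list(c("AAAACCCCGGGGTTTT", "ACGTACGTACGTACGT"))
  res <- count_guides(data.frame(cell_barcode = character(0),
                                 guide_id = character(0),
                                 umi = character(0)), cells, lib)
  expect_equal(sum(res$matrix), 0)
  expect_equal(dim(res$matrix), c(2L, 6L))
  expect_equal(res$report$n_matched_reads, 0)
})

test_that("counts are invariant to read order in exact mode", {
  set.seed(21)
  lib <- toy_library()
  wl <- random_barcodes(10)
  cells <- barcode_list(wl)
  n <- 300
  rec <- data.frame(
    cell_barcode = sample(wl, n, replace = TRUE),
    guide_id = sample(lib$guide_id, n, replace = TRUE),
    umi = vapply(seq_len(n), function(.)
      paste(sample(c("A", "C", "G", "T"), 12, replace = TRUE),
            collapse = ""), character(1)),
    stringsAsFactors = FALSE)
  m1 <- count_guides(rec, cells, lib)$matrix
  m2 <- count_guides(rec[sample(n), ], cells, lib)$matrix
  expect_equal(as.matrix(m1), as.matrix(m2))
  # sum of entries <= matched reads, equal iff triples unique
  expect_lte(sum(m1), n)
  expect_equal(sum(m1),
               nrow(unique(rec[c("cell_barcode", "guide_id", "umi")])))
})

test_that("matrix rows honour the barcode translation table", {
  lib <- toy_library()
  canonical <- c("AAAACCCCGGGGTTTT", "ACGTACGTACGTACGT")
  captured <- c("TTTTGGGGCCCCAAAA", "CATGCATGCATGCATG")
  cells <- barcode_list(canonical, setNames(canonical, captured))
  rec <- data.frame(cell_barcode = captured[2], guide_id = "NTC1_PS1",
                    umi = strrep("C", 12), stringsAsFactors = FALSE)
  m <- count_guides(rec, cells, lib)$matrix
  expect_equal(as.numeric(m[canonical[2], "NTC1_PS1"]), 1)
  expect_equal(sum(m), 1)
})
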
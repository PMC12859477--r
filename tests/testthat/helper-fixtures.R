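# Shared fixtures: a hand-written 3-vector dual-guide toy library whose
# protospacers are mutually far apart in Hamming distance, plus small
# generators used across test files.

toy_library <- function() {
  guide_library(data.frame(
    guide_id = c("GATA5_PS1", "GATA5_PS2", "NEUROG2_PS1", "NEUROG2_PS2",
                 "NTC1_PS1", "NTC1_PS2"),
    protospacer = c("GATTACAGATTACAGATTAC",
                    "CCGGTTAACCGGTTAACCGG",
                    "ACGTACGTACGTACGTACGT",
                    "TTTTCCCCAAAAGGGGTTTT",
                    "AGAGAGAGAGCTCTCTCTCT",
                    "GCGCGCATATGCGCGCATAT"),
    target = c("GATA5", "GATA5", "NEUROG2", "NEUROG2", "NTC1", "NTC1"),
    vector_id = c("V1", "V1", "V2", "V2", "V3", "V3"),
    stringsAsFactors = FALSE
  ))
}

# Library where the same gene is hit by two different vectors (tests
# cross-vector congruence).
cross_vector_library <- function() {
  guide_library(data.frame(
    guide_id = c("TP53_A1", "TP53_A2", "TP53_B1", "TP53_B2"),
    protospacer = c("GATTACAGATTACAGATTAC",
                    "CCGGTTAACCGGTTAACCGG",
                    "ACGTACGTACGTACGTACGT",
                    "TTTTCCCCAAAAGGGGTTTT"),
    target = "TP53",
    vector_id = c("VA", "VA", "VB", "VB"),
    stringsAsFactors = FALSE
  ))
}

random_barcodes <- function(n, len = 16L) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n)
  bcs <- apply(m, 1, paste, collapse = "")
  while (anyDuplicated(bcs))
    bcs[duplicated(bcs)] <- random_barcodes(sum(duplicated(bcs)), len)
  bcs
}

# Draw counts from the guide-count mixture at given parameters.
rmixture_counts <- function(n, pi, w0, mu_lo, r_lo, mu_hi, r_hi) {
  hi <- runif(n) < pi
  x <- integer(n)
  x[hi] <- rnbinom(sum(hi), size = r_hi, mu = mu_hi)
  n_lo <- sum(!hi)
  x[!hi] <- rbinom(n_lo, 1L, 1 - w0) * rnbinom(n_lo, size = r_lo, mu = mu_lo)
  x
}

# A simple calls data.frame for assignment tests: every (cell, guide) pair
# of `lib` for the given cells, expressed exactly for the pairs listed.
calls_fixture <- function(cells, lib, expressed_pairs) {
  df <- expand.grid(cell_barcode = cells, guide_id = lib$guide_id,
                    stringsAsFactors = FALSE)
  key <- paste(df$cell_barcode, df$guide_id)
  df$count <- 0L
  df$posterior <- 0.01
  df$expressed <- key %in% expressed_pairs
  df$count[df$expressed] <- 50L
  df$posterior[df$expressed] <- 0.99
  df
}
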
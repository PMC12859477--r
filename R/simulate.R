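#' Simulation configuration for synthetic guide-capture data
#'
#' The generator emulates the statistical structure the calling model
#' assumes: each cell takes up `Poisson(moi)` dual-guide vectors (low MOI,
#' so most cells receive at most one), each received vector contributes
#' high-mean negative binomial UMI counts to each of its protospacers, and
#' *every* (cell, guide) pair additionally receives zero-inflated negative
#' binomial ambient counts — the background created by free guide RNA in
#' the cell suspension.
#'
#' Defaults are the screen-like regime used throughout the package's
#' validation: MOI 0.1, strong expressing component (`mu_hi = 100`,
#' `r_hi = 5`) well separated from a sparse ambient background
#' (`w0 = 0.7`, `mu_lo = 0.5`, `r_lo = 1`).
#'
#' @param n_cells Number of cells.
#' @param lib A [guide_library()]; default [example_guide_library()].
#' @param moi Mean vectors per cell (Poisson), >= 0.
#' @param mu_hi,r_hi Expressing NB per protospacer of a received vector.
#' @param w0,mu_lo,r_lo Ambient ZINB applied to every (cell, guide).
#' @param seed Integer seed; identical configs give identical output.
#' @param rho Mean reads per UMI for read-level output (reads per molecule
#'   `~ 1 + Geometric(1/rho)`).
#' @param eps Per-base substitution error rate for read-level output,
#'   in `[0, 0.1]`.
#' @param layout A [read_layout()] for read-level output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cells = 5000L, lib = example_guide_library(),
                       moi = 0.1, mu_hi = 100, r_hi = 5,
                       w0 = 0.7, mu_lo = 0.5, r_lo = 1,
                       seed = 1L, rho = 4, eps = 0.005,
                       layout = read_layout()) {
  stopifnot(n_cells >= 1, moi >= 0, mu_hi > 0, r_hi > 0,
            w0 >= 0, w0 < 1, mu_lo > 0, r_lo > 0,
            rho >= 1, eps >= 0, eps <= 0.1,
            inherits(lib, "guide_library"), inherits(layout, "read_layout"))
  structure(list(n_cells = as.integer(n_cells), lib = lib, moi = moi,
                 mu_hi = mu_hi, r_hi = r_hi, w0 = w0, mu_lo = mu_lo,
                 r_lo = r_lo, seed = as.integer(seed), rho = rho,
                 eps = eps, layout = layout),
            class = "sim_config")
}

#' A screen-shaped example guide library
#'
#' Deterministically generated dual-guide library with the shape of a
#' small CRISPRi screen: 20 targeting vectors (2 protospacers each against
#' one gene) plus 6 non-targeting vectors, 52 guides in total. Each
#' non-targeting vector carries its own target label so that two different
#' NT vectors in one cell read as a doublet.
#'
#' @param n_targeting,n_nt Vector counts (defaults 20 and 6).
#' @param ps_len Protospacer length (default 20).
#' @return A [guide_library()].
#' @export
example_guide_library <- function(n_targeting = 20L, n_nt = 6L,
                                  ps_len = 20L) {
  n_vec <- n_targeting + n_nt
  seqs <- local_seed(20260925L, {
    unique_random_dna(2L * n_vec, ps_len)
  })
  gene <- c(sprintf("GENE%02d", seq_len(n_targeting)),
            sprintf("NTC%d", seq_len(n_nt)))
  vec <- c(sprintf("V_%s", gene))
  guide_library(data.frame(
    guide_id = paste0(rep(gene, each = 2), "_PS", 1:2),
    protospacer = seqs,
    target = rep(gene, each = 2),
    vector_id = rep(vec, each = 2),
    stringsAsFactors = FALSE
  ))
}

# Run code under a temporary RNG state.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n, len) {
  if (n == 0) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n)
  apply(m, 1, paste, collapse = "")
}

unique_random_dna <- function(n, len) {
  out <- random_dna(n, len)
  while (anyDuplicated(out))
    out[duplicated(out)] <- random_dna(sum(duplicated(out)), len)
  out
}

#' Simulate a truth-labelled cell x guide count matrix
#'
#' Per cell, `k ~ Poisson(moi)` vectors are drawn without replacement
#' (capped at the library size); each received vector adds
#' `NB(mu_hi, r_hi)` counts to each of its protospacers; every
#' (cell, guide) pair receives `ZINB(w0, mu_lo, r_lo)` ambient counts on
#' top. Fully reproducible from `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return List with `matrix` (observed counts, [guide_count_matrix()]),
#'   `truth` (`cells`: per-cell received vectors, true category and
#'   target; `signal`, `ambient`: the two count layers, which sum to the
#'   observed matrix), `cells` (a [barcode_list()]) and `cfg`.
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  lib <- cfg$lib
  vectors <- unique(lib$vector_id)
  n_vec <- length(vectors)
  n_g <- nrow(lib)
  local_seed(cfg$seed, {
    barcodes <- unique_random_dna(cfg$n_cells, 16L)
    k <- pmin(stats::rpois(cfg$n_cells, cfg$moi), n_vec)
    received <- lapply(seq_len(cfg$n_cells), function(i) {
      if (k[i] == 0) character(0) else sample(vectors, k[i])
    })
    # signal layer: one NB draw per (cell, protospacer-of-received-vector)
    cell_ix <- rep(seq_len(cfg$n_cells), k)
    vec_ix <- match(unlist(received), lib$vector_id)  # first guide row
    # expand vectors to their guides
    guides_of <- split(seq_len(n_g), lib$vector_id)
    sig_cell <- integer(0); sig_guide <- integer(0)
    if (length(cell_ix) > 0) {
      per_vec_guides <- guides_of[unlist(received)]
      reps <- lengths(per_vec_guides)
      sig_cell <- rep(cell_ix, reps)
      sig_guide <- unlist(per_vec_guides, use.names = FALSE)
    }
    sig_x <- if (length(sig_cell)) {
      stats::rnbinom(length(sig_cell), size = cfg$r_hi, mu = cfg$mu_hi)
    } else numeric(0)
    signal <- Matrix::sparseMatrix(i = sig_cell, j = sig_guide, x = sig_x,
                                   dims = c(cfg$n_cells, n_g))
    # ambient layer over every (cell, guide)
    N <- cfg$n_cells * n_g
    amb <- stats::rbinom(N, 1L, 1 - cfg$w0) *
      stats::rnbinom(N, size = cfg$r_lo, mu = cfg$mu_lo)
    nz <- which(amb > 0)
    ambient <- Matrix::sparseMatrix(
      i = ((nz - 1L) %% cfg$n_cells) + 1L,
      j = ((nz - 1L) %/% cfg$n_cells) + 1L,
      x = amb[nz], dims = c(cfg$n_cells, n_g))

    observed <- guide_count_matrix(signal + ambient, barcodes, lib$guide_id)
    truth_cells <- data.frame(
      cell_barcode = barcodes,
      vectors = vapply(received, paste, character(1), collapse = ","),
      n_vectors = k,
      category = vapply(seq_len(cfg$n_cells), function(i) {
        true_category(received[[i]], lib)
      }, character(1)),
      target = vapply(seq_len(cfg$n_cells), function(i) {
        v <- received[[i]]
        t <- unique(lib$target[lib$vector_id %in% v])
        if (length(t) == 1) t else NA_character_
      }, character(1)),
      stringsAsFactors = FALSE
    )
    dimnames(signal) <- dimnames(ambient) <- dimnames(observed)
    list(matrix = observed,
         truth = list(cells = truth_cells, signal = signal,
                      ambient = ambient),
         cells = barcode_list(barcodes),
         cfg = cfg)
  })
}

# True category under the caller's scheme: all protospacers of a received
# vector are expressed, so one vector with 2 guides is a congruent pair.
true_category <- function(vecs, lib) {
  if (length(vecs) == 0) return("unassigned")
  rows <- lib$vector_id %in% vecs
  targets <- unique(lib$target[rows])
  if (length(targets) > 1) return("doublet")
  if (sum(rows) >= 2) "singlet_2ps" else "singlet_1ps"
}

#' Emit raw guide-capture FASTQ reads for a simulated matrix
#'
#' Every UMI (matrix count) becomes `1 + Geometric(1/rho)` reads. The
#' barcode stream read carries the cell barcode at its layout offset; the
#' protospacer stream read carries the UMI at its offset, then filler, the
#' protospacer, the capture-sequence anchor, and filler to a fixed read
#' length. Substitution errors hit every base i.i.d. at rate `eps`.
#'
#' @param sim Output of [simulate_counts()].
#' @param out_dir Output directory; receives `guides_R1.fastq.gz` /
#'   `guides_R2.fastq.gz` (or one file when all elements share a stream),
#'   plus `truth_umis.tsv`.
#' @return List with `fastq` (paths in stream order), `truth_umis`
#'   (data.frame cell/guide/umi), invisibly reproducible from the config
#'   seed.
#' @export
simulate_fastq <- function(sim, out_dir) {
  cfg <- sim$cfg
  layout <- cfg$layout
  lib <- cfg$lib
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(methods::as(sim$matrix, "generalMatrix"), "TsparseMatrix")
  n_streams <- max(layout$bc_stream, layout$umi_stream, layout$ps_stream)
  paths <- file.path(out_dir, sprintf("guides_R%d.fastq.gz",
                                      seq_len(n_streams)))

  local_seed(cfg$seed + 1L, {
    cell <- rownames(sim$matrix)[m@i + 1L]
    guide <- colnames(sim$matrix)[m@j + 1L]
    n_umi_entry <- as.integer(m@x)
    total_umis <- sum(n_umi_entry)
    if (total_umis == 0) {
      for (p in paths) { con <- gzfile(p, "wb"); close(con) }
      truth <- data.frame(cell_barcode = character(0),
                          guide_id = character(0), umi = character(0))
      utils::write.table(truth, file.path(out_dir, "truth_umis.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      return(list(fastq = paths, truth_umis = truth))
    }
    u_cell <- rep(cell, n_umi_entry)
    u_guide <- rep(guide, n_umi_entry)
    umi <- random_dna(total_umis, layout$umi_len)
    # distinct UMIs within each (cell, guide)
    key <- paste(u_cell, u_guide, sep = "\r")
    while (anyDuplicated(paste(key, umi, sep = "\r"))) {
      dup <- duplicated(paste(key, umi, sep = "\r"))
      umi[dup] <- random_dna(sum(dup), layout$umi_len)
    }
    n_reads <- 1L + stats::rgeom(total_umis, prob = 1 / cfg$rho)
    r_cell <- rep(u_cell, n_reads)
    r_guide <- rep(u_guide, n_reads)
    r_umi <- rep(umi, n_reads)
    n <- length(r_cell)
    ps <- lib$protospacer[match(r_guide, lib$guide_id)]

    streams <- vector("list", n_streams)
    bc_read_len <- layout$bc_offset + layout$bc_len
    bc_body <- if (layout$bc_rc) {
      as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(r_cell)))
    } else r_cell
    streams[[layout$bc_stream]] <- paste0(
      filler_dna(n, layout$bc_offset), bc_body)
    ps_read <- paste0(filler_dna(n, layout$umi_offset), r_umi,
                      filler_dna(n, 8L), ps, layout$anchor)
    tail_len <- max(0L, 90L - nchar(ps_read)[1])
    ps_read <- paste0(ps_read, filler_dna(n, tail_len))
    if (layout$ps_stream == layout$umi_stream) {
      streams[[layout$ps_stream]] <- ps_read
    } else {
      streams[[layout$umi_stream]] <- paste0(
        filler_dna(n, layout$umi_offset), r_umi)
      streams[[layout$ps_stream]] <- ps_read
    }
    if (layout$bc_stream == layout$ps_stream)
      stop("simulator requires the barcode on its own stream")
    for (s in seq_len(n_streams)) {
      if (is.null(streams[[s]])) streams[[s]] <- filler_dna(n, bc_read_len)
      streams[[s]] <- mutate_seqs(streams[[s]], cfg$eps)
    }
    ids <- sprintf("@read%07d", seq_len(n))
    for (s in seq_len(n_streams)) {
      qual <- strrep("I", nchar(streams[[s]]))
      con <- gzfile(paths[s], "wb")
      writeLines(rbind(ids, streams[[s]], "+", qual), con)
      close(con)
    }
    truth <- data.frame(cell_barcode = u_cell, guide_id = u_guide,
                        umi = umi, stringsAsFactors = FALSE)
    truth <- truth[order(truth$cell_barcode, truth$guide_id, truth$umi,
                         method = "radix"), ]
    utils::write.table(truth, file.path(out_dir, "truth_umis.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(fastq = paths, truth_umis = truth)
  })
}

filler_dna <- function(n, len) {
  if (len == 0) return(rep("", n))
  random_dna(n, len)
}

# i.i.d. substitutions at rate eps; a hit base becomes one of the three
# other bases uniformly.
mutate_seqs <- function(seqs, eps) {
  if (eps <= 0 || length(seqs) == 0) return(seqs)
  lens <- nchar(seqs)
  stopifnot(length(unique(lens)) == 1)
  L <- lens[1]
  if (L == 0) return(seqs)
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)),
                  nrow = length(seqs), byrow = TRUE)
  hit <- which(matrix(stats::runif(length(chars)) < eps, nrow = nrow(chars)))
  if (length(hit) > 0) {
    bases <- c("A", "C", "G", "T")
    repl <- vapply(chars[hit], function(b) sample(bases[bases != b], 1),
                   character(1))
    chars[hit] <- repl
  }
  apply(chars, 1, paste, collapse = "")
}
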
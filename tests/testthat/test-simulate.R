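test_that("MOI zero leaves only ambient counts and unassigned truth", {
  cfg <- sim_config(n_cells = 300, moi = 0, seed = 3)
  sim <- simulate_counts(cfg)
  expect_equal(sum(sim$truth$signal), 0)
  expect_equal(as.matrix(sim$matrix), as.matrix(sim$truth$ambient),
               ignore_attr = TRUE)
  expect_true(all(sim$truth$cells$category == "unassigned"))
})

test_that("vector uptake matches the Poisson fraction at MOI 0.1", {
  cfg <- sim_config(n_cells = 10000, moi = 0.1, seed = 5)
  sim <- simulate_counts(cfg)
  frac <- mean(sim$truth$cells$n_vectors > 0)
  p <- 1 - exp(-0.1)
  se <- sqrt(p * (1 - p) / 10000)
  expect_lt(abs(frac - p), 3 * se)
})

test_that("the observed matrix is exactly signal plus ambient", {
  cfg <- sim_config(n_cells = 500, moi = 0.2, seed = 9)
  sim <- simulate_counts(cfg)
  expect_equal(as.matrix(sim$matrix),
               as.matrix(sim$truth$signal + sim$truth$ambient),
               ignore_attr = TRUE)
  expect_true(all(sim$matrix@x >= 0))
})

test_that("identical configs reproduce byte-identical artifacts", {
  cfg <- sim_config(n_cells = 120, seed = 77, eps = 0.01)
  s1 <- simulate_counts(cfg)
  s2 <- simulate_counts(cfg)
  expect_identical(as.matrix(s1$matrix), as.matrix(s2$matrix))
  expect_identical(s1$truth$cells, s2$truth$cells)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_count_matrix(s1$matrix, d1)
  write_count_matrix(s2$matrix, d2)
  simulate_fastq(s1, d1)
  simulate_fastq(s2, d2)
  for (f in c("matrix.mtx", "barcodes.tsv", "features.tsv",
              "truth_umis.tsv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  # gz members embed no timestamp-dependent payload difference
  expect_identical(readLines(file.path(d1, "guides_R1.fastq.gz")),
                   readLines(file.path(d2, "guides_R1.fastq.gz")))
})

test_that("signal column sums concentrate around n_receivers * mu_hi", {
  cfg <- sim_config(n_cells = 4000, moi = 0.5, seed = 13)
  sim <- simulate_counts(cfg)
  lib <- cfg$lib
  received <- strsplit(sim$truth$cells$vectors, ",", fixed = TRUE)
  for (j in sample(nrow(lib), 6)) {
    vec <- lib$vector_id[j]
    n_recv <- sum(vapply(received, function(v) vec %in% v, logical(1)))
    tot <- sum(sim$truth$signal[, j])
    if (n_recv == 0) { expect_equal(tot, 0); next }
    sd_tot <- sqrt(n_recv * (cfg$mu_hi + cfg$mu_hi^2 / cfg$r_hi))
    expect_lt(abs(tot - n_recv * cfg$mu_hi), 4 * sd_tot)
  }
})

test_that("error-free single-read FASTQs reproduce the matrix exactly", {
  cfg <- sim_config(n_cells = 60, moi = 0.3, seed = 7, rho = 1, eps = 0)
  sim <- simulate_counts(cfg)
  d <- withr::local_tempdir()
  fq <- simulate_fastq(sim, d)
  expect_equal(nrow(fq$truth_umis), sum(sim$matrix))
  res <- count_fastq(fq$fastq, cfg$layout, cfg$lib, sim$cells, "exact")
  expect_identical(as.matrix(res$matrix), as.matrix(sim$matrix))
  expect_equal(res$report$drops$no_anchor, 0)
})

test_that("an all-zero matrix yields empty FASTQ streams", {
  cfg <- sim_config(n_cells = 30, moi = 0, w0 = 0.99, mu_lo = 1e-3,
                    seed = 2)
  sim <- simulate_counts(cfg)
  sim$matrix[] <- 0
  d <- withr::local_tempdir()
  fq <- simulate_fastq(sim, d)
  for (p in fq$fastq) expect_length(readLines(p), 0)
  expect_equal(nrow(fq$truth_umis), 0)
})

test_that("simulated truth categories follow the received-vector targets", {
  cfg <- sim_config(n_cells = 2000, moi = 0.4, seed = 19)
  sim <- simulate_counts(cfg)
  tr <- sim$truth$cells
  lib <- cfg$lib
  i <- which(tr$n_vectors == 1)[1]
  expect_equal(tr$category[i], "singlet_2ps")   # dual-guide vector
  multi <- which(tr$n_vectors >= 2)
  for (i in head(multi, 10)) {
    vecs <- strsplit(tr$vectors[i], ",")[[1]]
    n_t <- length(unique(lib$target[lib$vector_id %in% vecs]))
    expect_equal(tr$category[i], if (n_t == 1) "singlet_2ps" else "doublet")
  }
})
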
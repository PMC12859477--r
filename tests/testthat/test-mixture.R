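test_that("weighted NB MLE recovers parameters and handles edge cases", {
  set.seed(31)
  x <- rnbinom(50000, size = 2, mu = 10)
  fit <- weighted_nb_mle(x, rep(1, length(x)))
  expect_lt(abs(fit$mu - 10) / 10, 0.02)
  expect_lt(abs(fit$r - 2) / 2, 0.10)
  # method-of-moments start agrees with the MLE within 25% on the same draw
  r_mom <- mean(x)^2 / (var(x) - mean(x))
  expect_lt(abs(fit$r - r_mom) / r_mom, 0.25)
  # zero variance: mu = the constant, r at the cap
  c_fit <- weighted_nb_mle(rep(7L, 20), rep(1, 20))
  expect_equal(c_fit$mu, 7)
  expect_equal(c_fit$r, exp(10))
  expect_error(weighted_nb_mle(c(1L, 2L), c(0, 0)), "effective sample")
  # weights matter: weighting out half the data reproduces a plain fit
  y <- c(x[1:5000], rep(999L, 5000))
  w <- rep(c(1, 0), each = 5000)
  wfit <- weighted_nb_mle(y, w)
  pfit <- weighted_nb_mle(x[1:5000], rep(1, 5000))
  expect_equal(wfit$mu, pfit$mu)
  expect_equal(wfit$r, pfit$r, tolerance = 1e-6)
})

test_that("EM recovers the generating mixture at the screen-like regime", {
  set.seed(101)
  x <- rmixture_counts(20000, pi = 0.1, w0 = 0.7, mu_lo = 0.5, r_lo = 1,
                       mu_hi = 100, r_hi = 5)
  fit <- fit_mixture(x)
  expect_equal(fit$status, "ok")
  expect_lt(abs(fit$params$mu_hi - 100) / 100, 0.10)
  expect_lt(abs(fit$params$pi - 0.1), 0.02)
  expect_gt(fit$params$mu_hi, fit$params$mu_lo)
  # EM trace never decreases
  expect_gt(min(diff(fit$loglik_trace)), -1e-8)
  # maximum likelihood dominates the true generating parameters
  truth <- mixture_params(0.1, 0.7, 0.5, 1, 100, 5)
  expect_gte(fit$loglik, mixture_loglik(x, truth))
})

test_that("degenerate inputs fall back instead of fitting", {
  all_zero <- rep(0L, 100)
  f <- fit_mixture(all_zero)
  expect_equal(f$status, "degenerate_fallback")
  expect_null(f$params)
  # fewer than min_positive nonzero cells
  f2 <- fit_mixture(c(rep(0L, 96), 5L, 9L, 1L, 2L))
  expect_equal(f2$status, "degenerate_fallback")
  # a guide nobody received: ambient-only counts carry no evidence of an
  # expressing component
  set.seed(42)
  amb <- rbinom(2000, 1, 0.3) * rnbinom(2000, size = 1, mu = 0.5)
  f3 <- fit_mixture(amb)
  expect_true(f3$status == "degenerate_fallback" ||
                f3$params$pi < 0.05)
  expect_error(fit_mixture(3L), "at least 2")
})

test_that("expression calls use a strict posterior threshold", {
  # exactly 0.5 is below the bar
  expect_false(is_expressed(0.5))
  expect_true(is_expressed(0.5 + 1e-12))
  expect_false(is_expressed(NA_real_))

  th <- mixture_params(0.1, 0.5, 0.5, 1, 100, 5)
  fit <- structure(list(status = "ok", params = th), class = "mixture_fit")
  x <- c(0L, 1L, 5L, 40L, 200L)
  calls <- classify_counts(fit, x, sprintf("BC%d", 1:5), "g1")
  expect_identical(calls$expressed, is_expressed(calls$posterior))
  # x = 0 dominated by the background -> never expressed
  expect_false(calls$expressed[1])
  expect_true(calls$expressed[5])

  # fallback guides call by raw count with absent posteriors
  fb <- structure(list(status = "degenerate_fallback", params = NULL),
                  class = "mixture_fit")
  fcalls <- classify_counts(fb, c(0L, 2L, 3L, 10L), sprintf("BC%d", 1:4),
                            "g2")
  expect_true(all(is.na(fcalls$posterior)))
  expect_identical(fcalls$expressed, c(FALSE, FALSE, TRUE, TRUE))
})

test_that("the call threshold count partitions cells monotonically", {
  # under equal dispersion the posterior crosses 1/2 once, so calls are
  # exactly {x >= x*}
  th <- mixture_params(0.08, 0, 1, 2, 80, 2)
  fit <- structure(list(status = "ok", params = th), class = "mixture_fit")
  x <- 0:500
  calls <- classify_counts(fit, x, sprintf("BC%d", x), "g1")
  xstar <- min(x[calls$expressed])
  expect_identical(calls$expressed, x >= xstar)
})

test_that("call_guides fits every column and emits one call per pair", {
  set.seed(55)
  n_cells <- 400
  bcs <- random_barcodes(n_cells)
  m <- cbind(
    g_hot = rmixture_counts(n_cells, 0.15, 0.7, 0.5, 1, 80, 5),
    g_cold = rbinom(n_cells, 1, 0.2) * rnbinom(n_cells, size = 1, mu = 0.4))
  gm <- guide_count_matrix(m, bcs, colnames(m))
  res <- call_guides(gm)
  expect_named(res$fits, c("g_hot", "g_cold"))
  expect_equal(nrow(res$calls), n_cells * 2)
  expect_equal(res$fits$g_hot$status, "ok")
  # calls agree with classify on the column
  manual <- classify_counts(res$fits$g_hot, as.integer(m[, 1]), bcs, "g_hot")
  expect_equal(res$calls[res$calls$guide_id == "g_hot", ]$expressed,
               manual$expressed)
})
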
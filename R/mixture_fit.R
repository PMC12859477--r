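#' Bundle mixture parameters for one guide
#'
#' The per-guide model for UMI counts across cells is a two-component
#' mixture: with probability `1 - pi` a cell draws from the zero-inflated
#' negative binomial background (ambient guide RNA; zero-inflation weight
#' `w0`, NB mean `mu_lo`, size `r_lo`) and with probability `pi` from the
#' plain negative binomial expressing component (`mu_hi`, `r_hi`). For
#' identifiability the expressing component is constrained to the larger
#' mean: `mu_hi > mu_lo`.
#'
#' @param pi Mixing weight of the expressing component, in (0, 1).
#' @param w0 Zero-inflation weight of the background, in `[0, 1)`.
#' @param mu_lo,r_lo Background NB mean and size, > 0.
#' @param mu_hi,r_hi Expressing NB mean and size, > 0; `mu_hi > mu_lo`.
#' @return A `mixture_params` list.
#' @export
mixture_params <- function(pi, w0, mu_lo, r_lo, mu_hi, r_hi) {
  stopifnot(pi > 0, pi < 1, w0 >= 0, w0 < 1,
            mu_lo > 0, r_lo > 0, mu_hi > 0, r_hi > 0,
            is.finite(c(mu_lo, r_lo, mu_hi, r_hi)))
  if (mu_hi <= mu_lo)
    stop("identifiability requires mu_hi > mu_lo")
  structure(list(pi = pi, w0 = w0, mu_lo = mu_lo, r_lo = r_lo,
                 mu_hi = mu_hi, r_hi = r_hi),
            class = "mixture_params")
}

#' Observed-data log-likelihood of the guide-count mixture
#'
#' `l(theta) = sum_cells log[(1 - pi) ZINB(x; w0, mu_lo, r_lo)
#'                           + pi NB(x; mu_hi, r_hi)]`,
#' computed in the log domain with log-sum-exp.
#'
#' @param counts Nonnegative integer UMI counts, one per cell; must be
#'   non-empty.
#' @param theta A [mixture_params()].
#' @return Scalar log-likelihood.
#' @export
mixture_loglik <- function(counts, theta) {
  if (length(counts) == 0) stop("empty counts vector")
  check_counts(counts)
  sum(component_lse(counts, theta))
}

# Per-observation log mixture density (vectorized).
component_lse <- function(x, theta) {
  llo <- log1p(-theta$pi) + zinb_logpmf(x, theta$w0, theta$mu_lo, theta$r_lo)
  lhi <- log(theta$pi) + nb_logpmf(x, theta$mu_hi, theta$r_hi)
  logsumexp2(llo, lhi)
}

#' Weighted maximum-likelihood fit of a negative binomial
#'
#' The EM M-step for one NB component: `mu` is the weighted mean, and the
#' size `r` solves the weighted score equation in `r` at fixed `mu`
#' (digamma form), found by bisection on `log r` over `[-10, 10]`. When the
#' weighted variance does not exceed the weighted mean the data are not
#' overdispersed and `r` is capped at `e^10` (Poisson-like); when the score
#' has no root in the bracket, the bracket end with the higher weighted
#' likelihood is returned.
#'
#' @param counts Nonnegative integer counts.
#' @param weights Nonnegative weights, `sum(weights) > 0`.
#' @return List `(mu, r)`.
#' @export
weighted_nb_mle <- function(counts, weights) {
  check_counts(counts)
  stopifnot(length(counts) == length(weights), all(weights >= 0))
  sw <- sum(weights)
  if (sw <= 0) stop("all-zero effective sample in weighted NB fit")
  mu <- sum(weights * counts) / sw
  if (mu <= 0) mu <- 1e-8          # responsibility mass entirely on zeros
  v <- sum(weights * (counts - mu)^2) / sw
  r_cap <- exp(10); r_floor <- exp(-10)
  if (v <= mu) return(list(mu = mu, r = r_cap))
  score <- function(logr) {
    r <- exp(logr)
    sum(weights * (digamma(counts + r) - digamma(r) +
                     log(r) - log(r + mu) + (mu - counts) / (r + mu)))
  }
  s_lo <- score(-10); s_hi <- score(10)
  if (s_lo > 0 && s_hi > 0) return(list(mu = mu, r = r_cap))
  if (s_lo < 0 && s_hi < 0) return(list(mu = mu, r = r_floor))
  root <- stats::uniroot(score, lower = -10, upper = 10, tol = 1e-10)
  list(mu = mu, r = exp(root$root))
}

# Moment estimate of NB size: r = mu^2 / (s^2 - mu); capped when
# underdispersed.
nb_moment_size <- function(mu, s2) {
  if (!is.finite(s2) || s2 <= mu || mu <= 0) return(exp(10))
  min(mu^2 / (s2 - mu), exp(10))
}

#' Fit the per-guide mixture by EM maximum likelihood
#'
#' EM over three expanded latent components — the structural zero (weight
#' `(1-pi) w0`), the background NB (weight `(1-pi)(1-w0)`) and the
#' expressing NB (weight `pi`). The E-step computes responsibilities from
#' the current parameters; the M-step re-estimates the weights as
#' responsibility means and each NB by [weighted_nb_mle()]. After every
#' M-step the identifiability constraint is enforced by swap-and-relabel:
#' if `mu_hi <= mu_lo` the two NB components exchange roles (a relabelling,
#' so the likelihood is untouched and EM monotonicity is preserved).
#' Convergence when the log-likelihood change drops below `tol`; the best
#' of `n_init` deterministic initializations (quantile splits at
#' 0.80, 0.85, 0.90, ...) by final likelihood is returned.
#'
#' Internally the E/M steps run on the tabulated counts (unique value,
#' multiplicity): responsibilities depend only on the count value, so this
#' is exact and makes the fit cost independent of the number of cells.
#'
#' @param counts Nonnegative integer UMI counts, one per cell (length >= 2);
#'   zeros are observations, not missing data.
#' @param max_iter,tol EM stopping rule (default 500 iterations, `1e-6`).
#' @param n_init Number of quantile-split initializations (default 3).
#' @param seed Recorded in the fit for provenance; the default fit is
#'   deterministic and consumes no randomness.
#' @param min_positive Guides with fewer than this many nonzero cells
#'   (default 5) are not fitted: status `degenerate_fallback`, and calling
#'   falls back to a count threshold (see [classify_counts()]).
#' @return A `mixture_fit`: `params` ([mixture_params()] or `NULL`),
#'   `loglik`, `loglik_trace`, `n_iter`, `converged`, `n_cells`,
#'   `n_positive`, `status` (`"ok"` or `"degenerate_fallback"`), `seed`.
#' @export
fit_mixture <- function(counts, max_iter = 500L, tol = 1e-6, n_init = 3L,
                        seed = NULL, min_positive = 5L) {
  check_counts(counts)
  if (length(counts) < 2) stop("need at least 2 observations")
  n <- length(counts)
  n_pos <- sum(counts > 0)
  base <- list(n_cells = n, n_positive = n_pos, seed = seed)
  if (n_pos < min_positive) {
    return(structure(c(base, list(params = NULL, loglik = NA_real_,
                                  loglik_trace = numeric(0), n_iter = 0L,
                                  converged = FALSE,
                                  status = "degenerate_fallback")),
                     class = "mixture_fit"))
  }

  tb <- table(counts)
  xs <- as.integer(names(tb))
  m <- as.numeric(tb)
  frac_zero <- mean(counts == 0)

  best <- NULL
  for (i in seq_len(n_init) - 1L) {
    init <- em_init(counts, 0.80 + 0.05 * i, frac_zero)
    if (is.null(init)) next
    fit <- try(em_run(xs, m, init, max_iter, tol), silent = TRUE)
    if (inherits(fit, "try-error") || !is.finite(fit$loglik)) next
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best))
    stop("all mixture initializations failed")
  # Evidence guard: a guide no cell received is pure ambient background and
  # a two-component fit on it is meaningless (the "expressing" component
  # just annexes the background's upper tail). Require the mixture to beat
  # a single-ZINB null fit by a BIC-style margin for its 3 extra
  # parameters; otherwise the guide is degenerate and falls back to the
  # count rule.
  ll_null <- fit_zinb_null(xs, m)
  status <- if (2 * (best$loglik - ll_null) > 3 * log(n)) "ok"
            else "degenerate_fallback"
  structure(c(base, best, list(loglik_null = ll_null, status = status)),
            class = "mixture_fit")
}

# Maximum likelihood of the single-component null: point mass at zero plus
# one NB (a plain ZINB, no expressing component), on tabulated counts.
fit_zinb_null <- function(xs, m) {
  n <- sum(m)
  mu0 <- max(sum(m * xs) / n, 1e-3)
  s2 <- sum(m * (xs - mu0)^2) / n
  u0 <- c(stats::qlogis(min(max(mean(xs == 0), 0.01), 0.99)),
          log(mu0), log(nb_moment_size(mu0, s2)))
  negll <- function(u) {
    w0 <- stats::plogis(u[1]); mu <- exp(u[2]); r <- exp(u[3])
    if (!is.finite(mu) || !is.finite(r)) return(1e300)
    lz <- ifelse(xs == 0L, log(w0), -Inf)
    lnb <- log1p(-w0) + stats::dnbinom(xs, size = r, mu = mu, log = TRUE)
    v <- -sum(m * logsumexp2(lz, lnb))
    if (!is.finite(v)) 1e300 else v
  }
  opt <- try(stats::optim(u0, negll, method = "BFGS",
                          control = list(maxit = 200, reltol = 1e-12)),
             silent = TRUE)
  if (inherits(opt, "try-error")) return(-Inf)
  -opt$value
}

# Quantile-split initialization: moments of the lower/upper parts seed the
# background/expressing NBs.
em_init <- function(counts, q, frac_zero) {
  qv <- stats::quantile(counts, q, names = FALSE, type = 7)
  upper <- counts[counts > qv]
  lower <- counts[counts <= qv]
  if (length(upper) == 0) upper <- counts[counts == max(counts)]
  if (length(lower) == 0 || length(upper) == 0) return(NULL)
  mu_lo <- max(mean(lower), 1e-3)
  r_lo <- nb_moment_size(mu_lo, stats::var(lower))
  mu_hi <- max(mean(upper), mu_lo * 1.01 + 1e-3)
  r_hi <- nb_moment_size(mu_hi, stats::var(upper))
  pi <- min(max(length(upper) / length(counts), 1e-4), 0.9)
  w0 <- max(0.1, frac_zero - exp(stats::dnbinom(0, size = r_lo, mu = mu_lo,
                                                log = TRUE)))
  w0 <- min(w0, 1 - 1e-6)
  list(pi = pi, w0 = w0, mu_lo = mu_lo, r_lo = r_lo,
       mu_hi = mu_hi, r_hi = r_hi)
}

# EM on tabulated counts xs with multiplicities m.
em_run <- function(xs, m, th, max_iter, tol) {
  n <- sum(m)
  iz <- xs == 0L
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  clamp <- function(p, lo = 1e-12, hi = 1 - 1e-12) min(max(p, lo), hi)
  for (iter in seq_len(max_iter)) {
    # E-step (log domain), three expanded components
    l0 <- ifelse(iz, log(clamp((1 - th$pi) * th$w0, 0)), -Inf)
    l0[!iz] <- -Inf
    if (th$w0 <= 0) l0[] <- -Inf
    l1 <- log(clamp((1 - th$pi) * (1 - th$w0))) +
      stats::dnbinom(xs, size = th$r_lo, mu = th$mu_lo, log = TRUE)
    l2 <- log(clamp(th$pi)) +
      stats::dnbinom(xs, size = th$r_hi, mu = th$mu_hi, log = TRUE)
    lse <- logsumexp2(logsumexp2(l0, l1), l2)
    ll <- sum(m * lse)
    trace <- c(trace, ll)
    if (is.finite(ll) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
    r0 <- exp(l0 - lse); r1 <- exp(l1 - lse); r2 <- exp(l2 - lse)
    # M-step
    a0 <- sum(m * r0) / n; a1 <- sum(m * r1) / n; a2 <- sum(m * r2) / n
    lo <- weighted_nb_mle(xs, m * r1)
    hi <- weighted_nb_mle(xs, m * r2)
    if (hi$mu <= lo$mu) {        # constraint: swap-and-relabel
      tmp <- lo; lo <- hi; hi <- tmp
      tmp <- a1; a1 <- a2; a2 <- tmp
    }
    th <- list(pi = clamp(a2), w0 = clamp(a0 / max(a0 + a1, 1e-300), 0),
               mu_lo = lo$mu, r_lo = lo$r, mu_hi = hi$mu, r_hi = hi$r)
  }
  if (!is.finite(ll)) stop("non-finite likelihood")
  # Quasi-Newton polish: EM crawls along the ridge where zero inflation
  # trades off against a low-dispersion background NB; a BFGS step from the
  # EM point sharpens convergence. Only an improvement is accepted, so the
  # likelihood trace stays non-decreasing.
  pol <- polish_fit(xs, m, th, ll)
  if (pol$loglik > ll) {
    th <- pol$theta
    ll <- pol$loglik
    trace <- c(trace, ll)
    converged <- converged || pol$converged
  }
  params <- mixture_params(th$pi, th$w0, th$mu_lo, th$r_lo,
                           max(th$mu_hi, th$mu_lo * (1 + 1e-12)), th$r_hi)
  list(params = params, loglik = ll, loglik_trace = trace,
       n_iter = iter, converged = converged)
}

# Direct likelihood maximization over an unconstrained reparameterization:
# logit(pi), logit(w0), log(mu_lo), log(r_lo), log(mu_hi - mu_lo) (gap form
# keeps the identifiability constraint), log(r_hi).
polish_fit <- function(xs, m, th, ll0) {
  clamp01 <- function(p) min(max(p, 1e-10), 1 - 1e-10)
  u0 <- c(stats::qlogis(clamp01(th$pi)), stats::qlogis(clamp01(th$w0)),
          log(th$mu_lo), log(min(th$r_lo, exp(10))),
          log(max(th$mu_hi - th$mu_lo, 1e-8)), log(min(th$r_hi, exp(10))))
  to_theta <- function(u) {
    mu_lo <- exp(u[3])
    list(pi = stats::plogis(u[1]), w0 = stats::plogis(u[2]),
         mu_lo = mu_lo, r_lo = exp(u[4]),
         mu_hi = mu_lo + exp(u[5]), r_hi = exp(u[6]))
  }
  negll <- function(u) {
    t <- to_theta(u)
    if (any(!is.finite(unlist(t))) || t$mu_lo <= 0 || t$r_lo <= 0 ||
        t$r_hi <= 0) return(1e300)
    iz <- xs == 0L
    l0 <- ifelse(iz, log(max((1 - t$pi) * t$w0, 1e-300)), -Inf)
    l1 <- log(max((1 - t$pi) * (1 - t$w0), 1e-300)) +
      stats::dnbinom(xs, size = t$r_lo, mu = t$mu_lo, log = TRUE)
    l2 <- log(max(t$pi, 1e-300)) +
      stats::dnbinom(xs, size = t$r_hi, mu = t$mu_hi, log = TRUE)
    v <- -sum(m * logsumexp2(logsumexp2(l0, l1), l2))
    if (!is.finite(v)) 1e300 else v
  }
  opt <- try(stats::optim(u0, negll, method = "BFGS",
                          control = list(maxit = 200, reltol = 1e-12)),
             silent = TRUE)
  if (inherits(opt, "try-error"))
    return(list(loglik = -Inf, theta = th, converged = FALSE))
  list(loglik = -opt$value, theta = to_theta(opt$par),
       converged = opt$convergence == 0)
}

#' Posterior probability of the expressing component
#'
#' `p(x) = pi NB(x; mu_hi, r_hi) / [pi NB(x; mu_hi, r_hi) +
#' (1 - pi) ZINB(x; w0, mu_lo, r_lo)]`, computed in the log domain.
#'
#' @param theta A [mixture_params()].
#' @param x Nonnegative integer counts (vectorized).
#' @return Posterior probabilities in `[0, 1]`.
#' @export
posterior_high <- function(theta, x) {
  check_counts(x)
  lhi <- log(theta$pi) + nb_logpmf(x, theta$mu_hi, theta$r_hi)
  llo <- log1p(-theta$pi) + zinb_logpmf(x, theta$w0, theta$mu_lo, theta$r_lo)
  exp(lhi - logsumexp2(lhi, llo))
}

#' Strict expression threshold on the posterior
#'
#' A cell expresses a guide only when the posterior strictly exceeds the
#' threshold: a posterior of exactly `tau` (default 1/2) is *not*
#' expressed. `NA` posteriors (fallback guides) are not expressed by this
#' rule either; they are called by the count fallback in
#' [classify_counts()].
#'
#' @param p Posterior probabilities (may contain `NA`).
#' @param tau Threshold, default 0.5.
#' @return Logical vector.
#' @export
is_expressed <- function(p, tau = 0.5) {
  !is.na(p) & p > tau
}

#' Call guide expression per cell from a fitted mixture
#'
#' A cell expresses the guide when the posterior probability of the
#' expressing component strictly exceeds 1/2 (a posterior of exactly 0.5 is
#' *not* expressed). Guides whose fit is a `degenerate_fallback` (too few
#' nonzero cells to estimate a mixture) are called by a raw count
#' threshold instead, with the posterior reported as `NA`.
#'
#' @param fit A `mixture_fit` from [fit_mixture()].
#' @param counts Per-cell UMI counts for this guide.
#' @param cell_barcodes Barcodes parallel to `counts`.
#' @param guide_id Guide identifier for the output rows.
#' @param fallback_min_count Count threshold for fallback guides
#'   (default 3: `expressed = count >= 3`).
#' @return Data frame of calls: `cell_barcode`, `guide_id`, `count`,
#'   `posterior`, `expressed`.
#' @export
classify_counts <- function(fit, counts, cell_barcodes,
                            guide_id = "guide", fallback_min_count = 3L) {
  check_counts(counts)
  stopifnot(length(counts) == length(cell_barcodes))
  if (fit$status == "ok") {
    p <- posterior_high(fit$params, counts)
    expressed <- is_expressed(p)
  } else {
    p <- rep(NA_real_, length(counts))
    expressed <- counts >= fallback_min_count
  }
  data.frame(cell_barcode = as.character(cell_barcodes),
             guide_id = guide_id,
             count = as.integer(counts),
             posterior = p,
             expressed = expressed,
             stringsAsFactors = FALSE)
}

#' Fit and call every guide of a count matrix
#'
#' Runs [fit_mixture()] on each guide column (all cells of the matrix,
#' zeros included) and [classify_counts()] on the fits.
#'
#' @param m Cell x guide count matrix ([guide_count_matrix()]).
#' @param ... Passed to [fit_mixture()].
#' @param fallback_min_count Passed to [classify_counts()].
#' @return List with `fits` (named list of `mixture_fit`) and `calls`
#'   (row-bound call data frame over all cell x guide pairs).
#' @export
call_guides <- function(m, ..., fallback_min_count = 3L) {
  stopifnot(!is.null(rownames(m)), !is.null(colnames(m)))
  fits <- list()
  calls <- vector("list", ncol(m))
  for (j in seq_len(ncol(m))) {
    g <- colnames(m)[j]
    x <- as.integer(m[, j])
    fits[[g]] <- fit_mixture(x, ...)
    calls[[j]] <- classify_counts(fits[[g]], x, rownames(m), g,
                                  fallback_min_count)
  }
  list(fits = fits, calls = do.call(rbind, calls))
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("Guide mixture fit:", x$status, "|", x$n_cells, "cells,",
      x$n_positive, "positive\n")
  if (x$status == "ok") {
    p <- x$params
    cat(sprintf("  pi=%.4g w0=%.4g mu_lo=%.4g r_lo=%.4g mu_hi=%.4g r_hi=%.4g\n",
                p$pi, p$w0, p$mu_lo, p$r_lo, p$mu_hi, p$r_hi))
    cat(sprintf("  loglik=%.4f after %d EM iterations (converged: %s)\n",
                x$loglik, x$n_iter, x$converged))
  }
  invisible(x)
}
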
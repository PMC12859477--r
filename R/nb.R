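#' Negative binomial log pmf (mean / size parameterization)
#'
#' `P(x) = Gamma(x+r) / (Gamma(r) x!) * (r/(r+mu))^r * (mu/(r+mu))^x`,
#' the mean/size form in which the identifiability constraint between the
#' background and expressing components (`mu_hi > mu_lo`) is directly
#' expressible. Thin wrapper over `stats::dnbinom` (log-gamma based, so
#' numerically stable for large `x` and `r`).
#'
#' @param x Nonnegative integer counts (vectorized).
#' @param mu Mean, > 0.
#' @param r Size (inverse-dispersion), > 0; `r -> Inf` is the Poisson limit.
#' @return `log P(x)`.
#' @export
nb_logpmf <- function(x, mu, r) {
  check_counts(x)
  stopifnot(mu > 0, r > 0)
  stats::dnbinom(x, size = r, mu = mu, log = TRUE)
}

#' Zero-inflated negative binomial log pmf
#'
#' `P(x) = w0 * 1[x = 0] + (1 - w0) * NB(x; mu, r)`, evaluated in the log
#' domain (log-sum-exp at `x = 0`). Models ambient background counts: a
#' point mass of structural zeros plus a low-mean NB.
#'
#' @param x Nonnegative integer counts (vectorized).
#' @param w0 Zero-inflation weight in `[0, 1)`.
#' @param mu,r NB mean and size, > 0.
#' @return `log P(x)`.
#' @export
zinb_logpmf <- function(x, w0, mu, r) {
  check_counts(x)
  stopifnot(w0 >= 0, w0 < 1)
  out <- log1p(-w0) + nb_logpmf(x, mu, r)
  if (w0 > 0) {
    iz <- x == 0
    if (any(iz)) out[iz] <- logsumexp2(log(w0), out[iz])
  }
  out
}

# log(exp(a) + exp(b)), elementwise-stable; handles -Inf operands.
logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log(exp(a - m) + exp(b - m))
  out[m == -Inf] <- -Inf
  out
}

check_counts <- function(x) {
  if (length(x) && (any(!is.finite(x)) || any(x < 0) || any(x != round(x))))
    stop("counts must be nonnegative integers")
  invisible(x)
}
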
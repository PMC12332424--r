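# Convergence diagnostics for replicate stochastic runs treated as chains.

#' Potential scale reduction factor across chains
#'
#' Gelman-Rubin style between/within variance ratio for `m` chains of
#' length `n` supplied as the columns of a matrix:
#' `PSRF = sqrt((W + (1 + 1/m) B/n) / W)` with `W` the mean within-chain
#' variance and `B/n` the variance of the chain means. The finite-sample
#' `(n-1)/n` shrinkage of the classic estimator is deliberately omitted so
#' that identical chains give exactly 1; values well above 1 still signal
#' disagreement between chains.
#'
#' @param chains Numeric matrix, one chain per column.
#' @return A single number >= 1 apart from numerical noise.
#' @export
psrf <- function(chains) {
  chains <- as.matrix(chains)
  m <- ncol(chains)
  assert_that(m >= 2, "psrf needs at least two chains")
  W <- mean(apply(chains, 2, var))
  B_over_n <- var(colMeans(chains))
  if (B_over_n == 0) return(1)
  if (W == 0) return(Inf)
  sqrt((W + (1 + 1 / m) * B_over_n) / W)
}

#' Effective sample size of a single chain
#'
#' Autocorrelation-based ESS, `n / (1 + 2 sum rho_k)`, with the sum
#' truncated by Geyer's initial positive sequence on paired
#' autocorrelations — the usual monotone, consistent truncation for MCMC
#' output. A constant chain is conventionally assigned ESS = n.
#'
#' @param x Numeric vector.
#' @return Estimated effective sample size.
#' @export
ess_chain <- function(x) {
  n <- length(x)
  if (n < 4 || var(x) == 0) return(as.numeric(n))
  lag_max <- min(n - 1, 10 * ceiling(sqrt(n)))
  rho <- drop(stats::acf(x, lag.max = lag_max, plot = FALSE,
                         demean = TRUE)$acf)
  # Pair sums Gamma_t = rho_{2t} + rho_{2t+1}; keep while positive.
  n_pairs <- floor((length(rho)) / 2)
  gam <- rho[2 * seq_len(n_pairs) - 1] + rho[2 * seq_len(n_pairs)]
  first_neg <- which(gam <= 0)
  keep <- if (length(first_neg) == 0) n_pairs else first_neg[1] - 1
  iact <- -1 + 2 * sum(gam[seq_len(keep)])
  iact <- max(iact, .Machine$double.eps)
  n / iact
}
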
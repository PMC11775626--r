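#' Split-chain Gelman-Rubin Rhat
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half. By default draws are rank-normalized first (pooled ranks mapped
#' through the normal quantile function), which makes the diagnostic robust
#' to heavy tails; `rank_normalized = FALSE` gives the classical split-chain
#' variant. Values near 1 indicate convergence; 1.1 is the conventional
#' threshold used by the fitting routines.
#'
#' @param draws iterations x chains matrix (a vector is treated as one
#'   chain, which is then split).
#' @param rank_normalized apply rank normalization first (default `TRUE`).
#' @return scalar Rhat; exactly 1 (with attribute `"constant"`) for a
#'   zero-variance parameter.
#' @export
rhat <- function(draws, rank_normalized = TRUE) {
  draws <- as.matrix(draws)
  if (stats::sd(draws) < .Machine$double.eps^0.5 || nrow(draws) < 4)
    return(structure(1, constant = TRUE))
  # split each chain in half
  n2 <- floor(nrow(draws) / 2)
  split <- cbind(draws[seq_len(n2), , drop = FALSE],
                 draws[nrow(draws) - n2 + seq_len(n2), , drop = FALSE])
  if (rank_normalized) {
    r <- matrix(rank(split, ties.method = "average"), nrow(split))
    split <- stats::qnorm((r - 3 / 8) / (length(split) + 1 / 4))
  }
  m <- ncol(split); n <- nrow(split)
  means <- colMeans(split)
  vars <- apply(split, 2, stats::var)
  B <- n * stats::var(means)
  W <- mean(vars)
  if (W < .Machine$double.eps) return(structure(1, constant = TRUE))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size of MCMC draws
#'
#' Autocorrelation-based ESS across chains: `ESS = m * n / tau` where
#' `tau = 1 + 2 * sum(rho_t)` uses combined-chain autocorrelations and the
#' sum is truncated by Geyer's initial monotone positive-pair sequence.
#'
#' @param draws iterations x chains matrix (vector = one chain).
#' @return scalar effective sample size (capped at the total draw count).
#' @export
ess <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws); m <- ncol(draws)
  N <- n * m
  if (stats::sd(draws) < .Machine$double.eps^0.5 || n < 4) return(N)
  vars <- apply(draws, 2, stats::var)
  W <- mean(vars)
  var_plus <- (n - 1) / n * W + if (m > 1) stats::var(colMeans(draws)) else W / n
  max_lag <- min(n - 1, 2000)
  acov <- vapply(seq_len(m), function(j)
    stats::acf(draws[, j], lag.max = max_lag, plot = FALSE,
               type = "covariance")$acf[, 1, 1],
    numeric(max_lag + 1))
  acov <- rowMeans(as.matrix(acov))            # lags 0..max_lag
  rho <- 1 - (W - acov) / var_plus             # rho[1] is lag 0
  npair <- floor((length(rho) - 1) / 2)
  tau <- rho[1]                                 # will accumulate 2*pairs - rho0 form
  s <- 0
  prev <- Inf
  for (k in seq_len(npair)) {
    pair <- rho[2 * k] + rho[2 * k + 1]
    if (pair < 0) break
    pair <- min(pair, prev)                     # enforce monotone decrease
    s <- s + pair
    prev <- pair
  }
  tau <- rho[1] + 2 * s
  tau <- max(tau, 1e-3)
  min(N / tau, N)
}
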
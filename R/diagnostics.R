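as_draws_array <- function(samples) {
  if (inherits(samples, "movegp_samples")) return(samples$draws)
  if (is.array(samples) && length(dim(samples)) == 3L) return(samples)
  stop("expected a movegp_samples object or a chain x draw x parameter array")
}

#' Gelman-Rubin potential scale reduction factor
#'
#' For each parameter, computes `sqrt(((n-1)/n * W + B/n) / W)` over `m`
#' chains of `n` draws, where `W` is the mean within-chain variance and
#' `B = n * var(chain means)` is the between-chain variance (so `B/n` is
#' the sample variance of the chain means, with the usual `1/(m-1)`
#' normalization). Values near 1 indicate the chains are sampling the same
#' distribution.
#'
#' @param samples A `movegp_samples` object or chain x draw x parameter
#'   array with at least 2 chains and 10 draws.
#' @return A list with `per_parameter` (named vector) and `max`.
#' @export
psrf <- function(samples) {
  a <- as_draws_array(samples)
  m <- dim(a)[1]; n <- dim(a)[2]
  if (m < 2L) stop("psrf needs at least 2 chains")
  if (n < 10L) stop("psrf needs at least 10 draws per chain")
  vals <- apply(a, 3, function(ch) {
    ch <- t(matrix(ch, m, n))  # draws x chains
    W <- mean(apply(ch, 2, stats::var))
    if (!is.finite(W) || W <= 0) stop("degenerate chain: zero within-chain variance")
    B <- n * stats::var(colMeans(ch))
    sqrt(((n - 1) / n * W + B / n) / W)
  })
  list(per_parameter = vals, max = max(vals))
}

#' Effective sample size of MCMC draws
#'
#' Autocorrelation-based ESS with Geyer's initial-positive-sequence
#' truncation: per-chain autocorrelations are averaged across chains,
#' summed over lag pairs until a pair sum turns negative, and
#' `ESS = m * n / (1 + 2 * sum(rho))`, capped at the total number of draws.
#'
#' @inheritParams psrf
#' @return A list with `per_parameter` and `min`.
#' @export
effective_sample_size <- function(samples) {
  a <- as_draws_array(samples)
  m <- dim(a)[1]; n <- dim(a)[2]
  if (n < 10L) stop("need at least 10 draws per chain")
  max_lag <- min(n - 1L, 1000L)
  vals <- apply(a, 3, function(ch) {
    ch <- t(matrix(ch, m, n))  # draws x chains
    rho <- rowMeans(vapply(seq_len(m), function(j) {
      v <- stats::var(ch[, j])
      if (!is.finite(v) || v <= 0) stop("degenerate chain: zero within-chain variance")
      stats::acf(ch[, j], lag.max = max_lag, plot = FALSE,
                 demean = TRUE)$acf[-1L, 1L, 1L]
    }, numeric(max_lag)))
    tau <- 1
    t <- 1L
    while (t + 1L <= max_lag) {
      pair <- rho[t] + rho[t + 1L]
      if (pair < 0) break
      tau <- tau + 2 * pair
      t <- t + 2L
    }
    min(m * n, m * n / tau)
  })
  list(per_parameter = vals, min = min(vals))
}

#' Convergence diagnostics table
#'
#' @param samples A `movegp_samples` object.
#' @return A data frame with posterior mean, sd, PSRF and ESS per parameter.
#' @export
diagnostics_table <- function(samples) {
  a <- as_draws_array(samples)
  pooled <- apply(a, 3, identity)
  r <- psrf(samples); e <- effective_sample_size(samples)
  data.frame(parameter = dimnames(a)[[3]],
             mean = colMeans(pooled), sd = apply(pooled, 2, stats::sd),
             psrf = r$per_parameter, ess = e$per_parameter,
             row.names = NULL)
}
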
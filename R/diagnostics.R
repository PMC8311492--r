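#' Split-chain convergence diagnostic (R-hat)
#'
#' Potential scale reduction computed after splitting each chain in half,
#' following the standard between/within variance ratio.
#'
#' @param draws Matrix of posterior draws, iterations x chains.
#' @return Scalar R-hat (1 at perfect mixing; values above ~1.1 flag
#'   non-convergence).
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  half <- n %/% 2L
  splits <- do.call(cbind, lapply(seq_len(ncol(draws)), function(j) {
    cbind(draws[seq_len(half), j], draws[(n - half + 1L):n, j])
  }))
  m <- ncol(splits)
  nn <- nrow(splits)
  means <- colMeans(splits)
  vars <- apply(splits, 2L, stats::var)
  w <- mean(vars)
  b <- nn * stats::var(means)
  if (w == 0) return(1)
  sqrt(((nn - 1) / nn * w + b / nn) / w)
}

#' Effective sample size
#'
#' Autocorrelation-based ESS using Geyer's initial monotone positive sequence
#' on the chain-averaged autocorrelations.
#'
#' @param draws Matrix of posterior draws, iterations x chains.
#' @return Scalar effective sample size.
#' @export
ess_basic <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  m <- ncol(draws)
  if (n < 4L) return(n * m)
  acov <- sapply(seq_len(m), function(j) {
    x <- draws[, j] - mean(draws[, j])
    stats::acf(x, lag.max = n - 1L, plot = FALSE, type = "covariance",
               demean = FALSE)$acf[, 1L, 1L]
  })
  acov <- rowMeans(acov)
  var0 <- acov[1L] * n / (n - 1)
  if (var0 == 0) return(n * m)
  rho <- acov / acov[1L]
  # Geyer pairs: P_t = rho(2t) + rho(2t+1); truncate at the first
  # non-positive pair and enforce monotone decrease.
  maxpairs <- length(rho) %/% 2L
  pair <- rho[2L * seq_len(maxpairs) - 1L] + rho[2L * seq_len(maxpairs)]
  nonpos <- which(pair <= 0)
  k <- if (length(nonpos)) nonpos[1L] - 1L else maxpairs
  if (k == 0L) return(n * m)
  pair <- cummin(pair[seq_len(k)])
  tau <- max(2 * sum(pair) - 1, 1)
  max(1, n * m / tau)
}
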
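# Independent oracles used across the suite.

# Marginal likelihood of one beta-binomial library by adaptive quadrature.
oracle_log_marginal <- function(k, N, a = 1, b = 1) {
  if (N == 0) return(0)
  f <- function(p) exp(lchoose(N, k) + k * log(p) + (N - k) * log1p(-p) +
                         (a - 1) * log(p) + (b - 1) * log1p(-p) - lbeta(a, b))
  log(stats::integrate(f, 0, 1, rel.tol = 1e-12, abs.tol = 0)$value)
}

# Shared-rate marginal likelihood of two libraries by adaptive quadrature.
oracle_log_shared <- function(k1, N1, k2, N2, a = 1, b = 1) {
  if (N1 + N2 == 0) return(0)
  f <- function(p) exp(lchoose(N1, k1) + lchoose(N2, k2) +
                         (k1 + k2) * log(p) +
                         (N1 + N2 - k1 - k2) * log1p(-p) +
                         (a - 1) * log(p) + (b - 1) * log1p(-p) - lbeta(a, b))
  log(stats::integrate(f, 0, 1, rel.tol = 1e-12, abs.tol = 0)$value)
}

# Brute-force metagene binning: walk every position, assign, sum.
oracle_metagene <- function(track, n_bins = 100L) {
  L <- length(track)
  prof <- numeric(n_bins)
  for (p in seq_len(L)) {
    bin <- floor((p - 1) * n_bins / L) + 1L
    prof[bin] <- prof[bin] + track[p]
  }
  prof
}

# Dense direct 2-D convolution with circular boundary.
oracle_conv2_circular <- function(m, k) {
  r <- (nrow(k) - 1L) %/% 2L
  n1 <- nrow(m); n2 <- ncol(m)
  out <- matrix(0, n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r) {
      acc <- acc + m[((i + di - 1) %% n1) + 1, ((j + dj - 1) %% n2) + 1] *
        k[di + r + 1, dj + r + 1]
    }
    out[i, j] <- acc
  }
  out
}
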
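# Shared fixtures, built in code.

# small panel used across tests: 40 strains, 2 chromosomes
toy_design <- function(n_inbred = 16, n_ri = 24, mice_per_strain = 2,
                       n_days = 5, n_markers = 120, missing_rate = 0.01,
                       n_cohorts = 6, ...) {
  panel_design(n_inbred = n_inbred, n_ri = n_ri,
               mice_per_strain = mice_per_strain, n_days = n_days,
               n_markers = n_markers,
               chromosome_lengths = c(chr1 = 100e6, chr2 = 80e6),
               missing_rate = missing_rate, n_cohorts = n_cohorts, ...)
}

toy_vc <- function() {
  variance_components(sigma1_sq = 0.3, sigma2_sq = 0.2, sigma3_sq = 0.02,
                      sigma4_sq = 0.02, sigma5_sq = 0, sigma6_sq = 0,
                      sigma_sq = 0.5)
}

# identity kinship over a genotype matrix's strains
identity_kinship <- function(genotypes) {
  ids <- rownames(genotypes$calls)
  K <- diag(length(ids))
  dimnames(K) <- list(ids, ids)
  class(K) <- c("kinship_matrix", "matrix")
  K
}

# brute-force marginal covariance from explicit random-effect design matrices:
# V = Z0 K0 Z0' + Z1 K3 Z1' + Z0 K5 Z1' + Z1 K5 Z0' + sigma^2 I,
# an independent construction of the model covariance used as oracle
brute_force_covariance <- function(vc, Gn, days) {
  n <- nrow(Gn); T_ <- length(days); N <- n * T_
  Z0 <- kronecker(diag(n), rep(1, T_))          # N x n intercept design
  Z1 <- kronecker(diag(n), days)                # N x n slope design
  I_n <- diag(n)
  K0 <- vc$sigma1_sq * Gn + vc$sigma2_sq * I_n
  K3 <- vc$sigma3_sq * Gn + vc$sigma4_sq * I_n
  K5 <- vc$sigma5_sq * Gn + vc$sigma6_sq * I_n
  Z0 %*% K0 %*% t(Z0) + Z1 %*% K3 %*% t(Z1) +
    Z0 %*% K5 %*% t(Z1) + Z1 %*% K5 %*% t(Z0) + vc$sigma_sq * diag(N)
}

# exact upper-tail Poisson probability by term-by-term summation (oracle):
# P(X >= k) summed upward from the k-th term until terms are negligible
poisson_tail_oracle <- function(k, lambda) {
  if (k <= 0) return(1)
  term <- exp(k * log(lambda) - lambda - lgamma(k + 1))
  total <- term
  i <- k
  while (term > total * 1e-18 && i < k + 10000) {
    i <- i + 1
    term <- term * lambda / i
    total <- total + term
  }
  total
}

# exact two-sided Fisher p by hypergeometric enumeration (oracle)
fisher_p_oracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(k) {
    exp(lchoose(c1, k) + lchoose(n - c1, r1 - k) - lchoose(n, r1))
  }, numeric(1))
  p_obs <- probs[a - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
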
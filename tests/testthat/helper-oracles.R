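# Independent oracles used across test files. These deliberately avoid the
# package's own numerical choices: dense brute-force quadrature for the
# purity posterior, full enumeration for the rank tests, and a bitmask
# assignment solver for factor matching.

# Dense double-marginalisation of the purity posterior: same 100-point rho
# grid as the reported posterior, but a 10^4-point trapezoid over kappa_n
# written independently of the package's integrator.
oracle_purity_probs <- function(N, n_kappa, mu, sigma,
                                rho_grid = seq(0, 1, length.out = 100),
                                n_kn = 10001L) {
  kn <- seq(0, 1, length.out = n_kn)
  h <- kn[2] - kn[1]
  z <- pnorm(1, mu, sigma) - pnorm(0, mu, sigma)
  dens <- dnorm(kn, mu, sigma) / z
  un <- sapply(rho_grid, function(r) {
    f0 <- dbinom(n_kappa, N, (1 - r) * kn) * dens
    f1 <- dbinom(n_kappa, N, pmin(r + (1 - r) * kn, 1)) * dens
    int0 <- h * (sum(f0) - (f0[1] + f0[n_kn]) / 2)
    int1 <- h * (sum(f1) - (f1[1] + f1[n_kn]) / 2)
    0.5 * (int0 + int1)
  })
  un / sum(un)
}

# Exact two-sided Wilcoxon rank-sum p by enumeration of all group-A subsets.
oracle_wilcoxon_exact <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n1)])
  idx <- utils::combn(length(pooled), n1)
  stats <- apply(idx, 2, function(ii) sum(r[ii]))
  mu <- mean(stats)
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# Exact Kruskal-Wallis p by enumeration of all assignments of the pooled
# values to the observed group sizes.
oracle_kw_exact <- function(values, groups) {
  groups <- factor(groups)
  sizes <- tabulate(groups)
  kw_stat <- function(g) {
    suppressWarnings(stats::kruskal.test(values, factor(g))$statistic)
  }
  obs <- kw_stat(as.integer(groups))
  perms <- plasmasig:::multiset_permutations(sizes)
  stats <- apply(perms, 1, kw_stat)
  mean(stats >= obs - 1e-9)
}

# Maximum-mean-cosine bijective matching between the columns of two
# nonnegative matrices (exact assignment via bitmask dynamic programming).
oracle_matched_cosine <- function(W_true, W_est) {
  cos_mat <- matrix(0, ncol(W_true), ncol(W_est))
  for (i in seq_len(ncol(W_true))) {
    for (j in seq_len(ncol(W_est))) {
      cos_mat[i, j] <- sum(W_true[, i] * W_est[, j]) /
        (sqrt(sum(W_true[, i]^2)) * sqrt(sum(W_est[, j]^2)))
    }
  }
  k <- nrow(cos_mat); m <- ncol(cos_mat)
  stopifnot(k <= 16)
  # assign each true column a distinct estimated column, maximising the sum
  best <- new.env(parent = emptyenv())
  solve <- function(i, used) {
    if (i > k) return(0)
    key <- paste(i, used)
    if (!is.null(best[[key]])) return(best[[key]])
    v <- -Inf
    for (j in seq_len(m)) {
      if (!bitwAnd(used, bitwShiftL(1L, j - 1L))) {
        v <- max(v, cos_mat[i, j] + solve(i + 1, bitwOr(used, bitwShiftL(1L, j - 1L))))
      }
    }
    best[[key]] <- v
    v
  }
  if (m < k) return(NA_real_)
  solve(1L, 0L) / k
}
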
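# Independent oracles used across the suite. These deliberately avoid the
# package's own computation paths.

# Random genotype matrix in {0, 1, 2}.
rand_geno <- function(n, m, maf = NULL) {
  if (is.null(maf)) {
    matrix(sample(0:2, n * m, replace = TRUE), n, m)
  } else {
    sapply(seq_len(m), function(j) rbinom(n, 2, maf[min(j, length(maf))]))
  }
}

# Brute-force OLS via the normal equations.
ols_oracle <- function(y, X) {
  beta <- solve(crossprod(X), crossprod(X, y))
  r <- y - X %*% beta
  list(beta = drop(beta), resid = drop(r),
       sigma2 = sum(r^2) / (length(y) - ncol(X)))
}

# Kernel ridge regression: h = K (K + lambda I)^{-1} r, penalty
# lambda = sigma2 / tau. Direct penalized least squares, independent of
# estimate_h_blup's formulation.
kernel_ridge_oracle <- function(K, r, lambda) {
  n <- nrow(K)
  alpha <- solve(K + diag(lambda, n), r)
  drop(K %*% alpha)
}

# Imhof-type numerical inversion of the characteristic function of
# sum_j lambda_j chisq(1)_j: second independent oracle for the exact null.
imhof_pvalue <- function(q, lambda) {
  lambda <- lambda[abs(lambda) > 1e-12 * max(abs(lambda))]
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
    rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    sin(theta) / (u * rho)
  }
  val <- stats::integrate(integrand, lower = 0, upper = Inf,
                          rel.tol = 1e-9, subdivisions = 2000L)$value
  min(max(0.5 + val / pi, 0), 1)
}

# Pointwise band membership for sorted uniform order statistics.
beta_band <- function(m, level = 0.95) {
  i <- seq_len(m)
  a <- (1 - level) / 2
  list(lower = qbeta(a, i, m - i + 1), upper = qbeta(1 - a, i, m - i + 1))
}

# Small covariate table for design tests.
toy_covariates <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(sample_id = sprintf("S%04d", seq_len(n)),
             Sex = rbinom(n, 1, 0.5),
             Age = rnorm(n, 49, 12),
             Smoking = rbinom(n, 1, 0.3),
             stringsAsFactors = FALSE)
}

# Tiny replicate-set-like world for fast scans.
tiny_config <- function(seed = 7, n_replicates = 5L, n = 80L) {
  sim_config(
    n_samples = n,
    genes = list(sim_gene("gA", n_snps = 4, rare_fraction = 0,
                          common_maf_range = c(0.1, 0.4)),
                 sim_gene("gB", n_snps = 3, rare_fraction = 0,
                          common_maf_range = c(0.1, 0.4)),
                 sim_gene("gC", n_snps = 5, rare_fraction = 0.5)),
    n_background_snps = 50L, subpop_trait_shift = 0,
    n_replicates = n_replicates, seed = seed)
}
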
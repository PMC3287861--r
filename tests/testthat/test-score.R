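test_that("fit_null matches closed forms and the normal-equations oracle", {
  # intercept-only: mean and sample variance
  fit <- fit_null(c(1, 2, 3), matrix(1, 3, 1))
  expect_equal(unname(fit$beta_hat), 2)
  expect_equal(fit$sigma2_hat, 1)
  expect_lt(max(abs(crossprod(fit$X, fit$residuals))), 1e-8)

  # y exactly linear in X -> degenerate
  X <- cbind(1, 1:10)
  fit_d <- fit_null(2 + 3 * (1:10), X)
  expect_true(fit_d$degenerate)
  expect_equal(fit_d$sigma2_hat, 0, tolerance = 1e-20)

  # random instance vs brute-force (X'X)^{-1} X'y
  set.seed(50)
  X <- cbind(1, matrix(rnorm(50 * 3), 50))
  y <- rnorm(50)
  fit <- fit_null(y, X)
  oracle <- ols_oracle(y, X)
  expect_equal(unname(fit$beta_hat), oracle$beta, tolerance = 1e-10)
  expect_equal(fit$residuals, oracle$resid, tolerance = 1e-10)
  expect_equal(fit$sigma2_hat, oracle$sigma2, tolerance = 1e-10)

  expect_error(fit_null(rnorm(3), cbind(1, diag(3))), "n > q")
})

test_that("score statistic: identity, zero and brute-force quadratic form", {
  set.seed(51)
  n <- 20
  X <- cbind(1, rnorm(n))
  y <- rnorm(n)
  fit <- fit_null(y, X)
  expect_equal(score_statistic(fit, diag(n)), (n - 2) / 2)
  expect_equal(score_statistic(fit, matrix(0, n, n)), 0)
  A <- matrix(rnorm(n * n), n); K <- crossprod(A)
  r <- fit$residuals
  expect_equal(score_statistic(fit, K),
               drop(t(r) %*% K %*% r) / (2 * fit$sigma2_hat))
  # PSD kernel -> nonnegative Q, always
  for (rep in 1:10) {
    G <- rand_geno(n, 3)
    expect_gte(score_statistic(fit, polynomial_kernel(G, 2, 0)), 0)
  }
})

test_that("Satterthwaite closed forms: identity kernel and rank-1 reduction", {
  set.seed(52)
  # K = identity, X = intercept: kappa = 1/2, nu = n - 1, p = P(chisq > n-1)
  for (n in c(2, 5, 30)) {
    fit <- fit_null(rnorm(n), matrix(1, n, 1))
    res <- satterthwaite_pvalue(fit, diag(n))
    expect_equal(res$kappa, 1 / 2)
    expect_equal(res$nu, n - 1)
    expect_equal(res$Q, (n - 1) / 2)
    expect_equal(res$p_value, pchisq(n - 1, n - 1, lower.tail = FALSE))
  }
  # single nonzero eigenvalue on the residual space -> nu = 1 and the
  # closed-form single chi-square p-value
  n <- 25
  X <- cbind(1, rnorm(n))
  y <- rnorm(n)
  fit <- fit_null(y, X)
  u <- rnorm(n)
  K <- tcrossprod(u)  # rank one
  res <- satterthwaite_pvalue(fit, K)
  expect_equal(res$nu, 1, tolerance = 1e-8)
  P0u <- u - qr.fitted(fit$qr, u)
  lam <- sum(u * P0u)
  p_closed <- pchisq(sum(u * fit$residuals)^2 / (fit$sigma2_hat * lam), 1,
                     lower.tail = FALSE)
  expect_equal(res$p_value, p_closed, tolerance = 1e-8)
})

test_that("degenerate kernels and fits give p = 1", {
  set.seed(53)
  n <- 15
  fit <- fit_null(rnorm(n), matrix(1, n, 1))
  # constant kernel: annihilated by the residual projection
  expect_equal(satterthwaite_pvalue(fit, matrix(1, n, n))$p_value, 1)
  expect_equal(satterthwaite_pvalue(fit, matrix(0, n, n))$p_value, 1)
  # all-zero gene -> constant (zero) interaction kernel via the full path
  G0 <- matrix(0L, n, 3, dimnames = list(sprintf("S%04d", 1:n), NULL))
  res <- test_gene(rnorm(n), model_spec("M12"), G0, toy_covariates(n))
  expect_equal(res$p_value, 1)
  expect_equal(res$method, "degenerate")
})

test_that("MC oracle agrees with closed form and with Imhof inversion", {
  set.seed(54)
  n <- 30
  X <- cbind(1, rnorm(n))
  y <- rnorm(n)
  fit <- fit_null(y, X)
  # rank-1 kernel: exact null is lambda/2 * chisq(1); place Q at the 95th
  # percentile and recover p ~ 0.05
  u <- rnorm(n)
  K <- tcrossprod(u)
  lam <- sum(u * (u - qr.fitted(fit$qr, u))) / 2
  Q95 <- lam * qchisq(0.95, 1)
  p_mc <- exact_pvalue_mc(fit, K, Q = Q95, n_draws = 1e5, seed = 9)
  expect_lt(abs(p_mc - 0.05), 3 * attr(p_mc, "se") + 1e-3)

  # all eigenvalues zero -> p = 1
  expect_equal(as.numeric(exact_pvalue_mc(fit, matrix(1, n, n) * 0,
                                          n_draws = 1e5, seed = 1)), 1)

  # random instance vs characteristic-function inversion
  G <- rand_geno(n, 4)
  K <- polynomial_kernel(G, 1, 0)
  Q <- score_statistic(fit, K)
  mm <- kernelGxE:::null_moments(fit, K)
  lambda <- eigen(mm$B, symmetric = TRUE, only.values = TRUE)$values / 2
  p_imhof <- imhof_pvalue(Q, lambda)
  p_mc <- exact_pvalue_mc(fit, K, Q, n_draws = 2e5, seed = 77)
  expect_lt(abs(p_mc - p_imhof), 0.002 + 3 * attr(p_mc, "se"))
  expect_error(exact_pvalue_mc(fit, K, Q, n_draws = 100), "1e5")
})

test_that("Satterthwaite moments are the exact null moments of Q", {
  set.seed(55)
  n <- 60
  X <- cbind(1, rnorm(n), rbinom(n, 1, 0.4))
  G <- rand_geno(n, 5, maf = c(0.05, 0.1, 0.2, 0.3, 0.4))
  K <- polynomial_kernel(G, 2, 0)
  V <- as.matrix(K)
  qrx <- qr(X)
  n_draws <- 1e4
  sigma2 <- 1.7
  # simulate Q under the null with KNOWN sigma2 (the moments mu, v are for
  # the sigma2-known statistic; plugging sigma2_hat is the approximation)
  Ysim <- matrix(rnorm(n * n_draws, 0, sqrt(sigma2)), n)
  R <- qr.resid(qrx, Ysim)
  Qs <- colSums(R * (V %*% R)) / (2 * sigma2)
  fit <- fit_null(Ysim[, 1], X)
  mm <- kernelGxE:::null_moments(fit, K)
  se_mean <- sd(Qs) / sqrt(n_draws)
  expect_lt(abs(mean(Qs) - mm$mu), 3 * se_mean)
  m4 <- mean((Qs - mean(Qs))^4)
  se_var <- sqrt((m4 - var(Qs)^2) / n_draws)
  expect_lt(abs(var(Qs) - mm$v), 3 * se_var)
})

test_that("p-values are invariant to location-scale changes of y", {
  set.seed(56)
  n <- 40
  X <- cbind(1, rnorm(n))
  y <- rnorm(n)
  G <- rand_geno(n, 4)
  for (K in list(polynomial_kernel(G, 2, 0), iis_kernel(G),
                 gaussian_kernel(G))) {
    p1 <- satterthwaite_pvalue(fit_null(y, X), K)$p_value
    p2 <- satterthwaite_pvalue(fit_null(3 + 2.5 * y, X), K)$p_value
    expect_equal(p1, p2, tolerance = 1e-8)
  }
})

test_that("BLUP limits and equivalence structure", {
  set.seed(57)
  n <- 30
  X <- cbind(1, rnorm(n))
  y <- rnorm(n)
  fit <- fit_null(y, X)
  # distinct continuous inputs + local bandwidth keep K comfortably full
  # rank (duplicated genotype rows would make interpolation impossible)
  Z <- matrix(rnorm(n * 5), n)
  K <- gaussian_kernel(Z, bandwidth = 0.5)
  expect_equal(estimate_h_blup(fit, K, 0), rep(0, n))
  # tau -> infinity: h interpolates the residuals
  h_inf <- estimate_h_blup(fit, K, 1e8)
  r <- fit$residuals
  expect_lt(sqrt(sum((h_inf - r)^2) / sum(r^2)), 1e-3)
  # equals kernel ridge with penalty sigma2 / tau
  tau <- 0.8
  h <- estimate_h_blup(fit, K, tau)
  expect_equal(h, kernel_ridge_oracle(as.matrix(K), r,
                                      fit$sigma2_hat / tau),
               tolerance = 1e-8)
})

test_that("test_gene: one-SNP linear kernel equals the single-SNP score test", {
  set.seed(58)
  n <- 80
  G <- rand_geno(n, 1, maf = 0.3)
  rownames(G) <- sprintf("S%04d", 1:n)
  cov <- toy_covariates(n, seed = 58)
  y <- rnorm(n)
  res <- test_gene(y, model_spec("M2", kernel_spec("linear")), G, cov,
                   gene_id = "snp1")
  # brute-force one-SNP variance-component score test: the weighted-chi-
  # square null has a single eigenvalue g'P0g, so p is exactly chisq(1)
  db <- build_design(model_spec("M2"), G, cov)
  fit <- fit_null(y, db$X)
  g <- as.numeric(G)
  P0g <- g - qr.fitted(fit$qr, g)
  p_oracle <- pchisq(sum(g * fit$residuals)^2 /
                       (fit$sigma2_hat * sum(g * P0g)), 1,
                     lower.tail = FALSE)
  expect_lt(abs(res$p_value - p_oracle), 0.01)
  expect_equal(res$gene_id, "snp1")

  # M10 reduces to M2 for a single SNP
  res10 <- test_gene(y, model_spec("M10", kernel_spec("linear")), G, cov)
  expect_equal(res10$p_value, res$p_value, tolerance = 1e-10)
})

test_that("all-zero exposure degenerates the interaction models", {
  set.seed(59)
  n <- 30
  G <- rand_geno(n, 4)
  rownames(G) <- sprintf("S%04d", 1:n)
  cov <- toy_covariates(n, seed = 59)
  cov$Smoking <- 0
  y <- rnorm(n)
  for (mid in c("M11", "M12")) {
    res <- test_gene(y, model_spec(mid), G, cov)
    expect_equal(res$p_value, 1)
    expect_equal(res$method, "degenerate")
  }
})

test_that("score_test_replicates matches per-replicate test_gene", {
  set.seed(60)
  n <- 50
  G <- rand_geno(n, 5)
  rownames(G) <- sprintf("S%04d", 1:n)
  cov <- toy_covariates(n, seed = 60)
  Y <- matrix(rnorm(n * 4), n)
  model <- model_spec("M12", kernel_spec("polynomial", 2))
  db <- build_design(model, G, cov)
  K <- build_kernel(model$kernel, db$kernel_input)
  batch <- score_test_replicates(Y, cbind(db$X, db$main_effect_block), K)
  for (j in 1:4) {
    single <- test_gene(Y[, j], model, G, cov)
    expect_equal(batch$p_value[j], single$p_value, tolerance = 1e-10)
    expect_equal(batch$Q[j], single$Q, tolerance = 1e-10)
  }
})
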
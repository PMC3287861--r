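# Variance-component score test for H0: tau = 0 in
#
#   y = X beta + h + e,   h ~ (0, tau * K),   e ~ N(0, sigma^2 I).
#
# The statistic is Q = r' K r / (2 sigma2_hat) with r the OLS residuals of
# the null fit. Under H0, Q is a weighted sum of chi-square(1) variables
# with weights equal to the eigenvalues of P0 K P0 / 2 (P0 the residual
# projection); the production path approximates this by a scaled chi-square
# kappa * chisq(nu) matched on the first two moments (Satterthwaite), and
# the Monte Carlo oracle samples the weighted sum exactly.

P_FLOOR <- 1e-300

#' Fit the null fixed-effects model
#'
#' Ordinary least squares of `y` on `X` (collinear columns pruned first),
#' with the REML-consistent residual variance `RSS / (n - q)`.
#'
#' @param y Numeric response vector.
#' @param X Fixed-effect design matrix (should include an intercept).
#' @return An object of class `null_fit` with elements `beta_hat`,
#'   `sigma2_hat`, `residuals`, `qr`, `X`, `n`, `q` and a `degenerate` flag
#'   (`TRUE` when `y` lies in the column space of `X`).
#' @export
fit_null <- function(y, X) {
  y <- as.numeric(y)
  X <- drop_collinear(as.matrix(X))
  n <- length(y)
  q <- ncol(X)
  if (nrow(X) != n) stop("`y` and `X` have different lengths", call. = FALSE)
  if (n <= q) stop("need n > q for the null fit", call. = FALSE)
  qrx <- qr(X)
  beta <- qr.coef(qrx, y)
  r <- qr.resid(qrx, y)
  rss <- sum(r^2)
  sigma2 <- rss / (n - q)
  scale_y <- mean(y^2) + .Machine$double.eps
  structure(list(beta_hat = beta, sigma2_hat = sigma2, residuals = r,
                 qr = qrx, X = X, y = y, n = n, q = q,
                 degenerate = sigma2 <= 1e-12 * scale_y,
                 cache = new.env(parent = emptyenv())),
            class = "null_fit")
}

#' @export
print.null_fit <- function(x, ...) {
  cat("<null_fit> n = ", x$n, ", q = ", x$q,
      ", sigma2_hat = ", format(x$sigma2_hat, digits = 4),
      if (x$degenerate) " (degenerate)" else "", "\n", sep = "")
  invisible(x)
}

# Null moments of Q via the projected kernel B = P0 K P0:
#   mu = tr(B) / 2,  v = tr(B^2) / 2 = sum(B * B) / 2.
# Cached per kernel on the fit object.
null_moments <- function(fit, K) {
  key <- if (inherits(K, "kernel_matrix")) K$input_hash else input_hash(K)
  hit <- fit$cache[[key]]
  if (!is.null(hit)) return(hit)
  V <- kernel_values(K)
  A <- V - qr.fitted(fit$qr, V)            # P0 K
  B <- A - t(qr.fitted(fit$qr, t(A)))      # P0 K P0
  B <- (B + t(B)) / 2
  out <- list(mu = sum(diag(B)) / 2, v = sum(B * B) / 2, B = B)
  fit$cache[[key]] <- out
  out
}

moments_degenerate <- function(mu, v, K) {
  kscale <- max(abs(diag(kernel_values(K))), .Machine$double.eps)
  mu <= 1e-10 * kscale || v <= (1e-10 * kscale)^2
}

#' Score statistic for the variance component
#'
#' `Q = r' K r / (2 sigma2_hat)`; nonnegative whenever `K` is positive
#' semidefinite.
#'
#' @param fit A [fit_null()] object.
#' @param K `kernel_matrix` or square matrix.
#' @return The statistic `Q` (0 for a degenerate fit).
#' @export
score_statistic <- function(fit, K) {
  stopifnot(inherits(fit, "null_fit"))
  if (fit$degenerate) return(0)
  V <- kernel_values(K)
  r <- fit$residuals
  drop(crossprod(r, V %*% r)) / (2 * fit$sigma2_hat)
}

score_test_result <- function(Q, kappa, nu, p, method,
                              model_id = NA_character_,
                              gene_id = NA_character_) {
  structure(list(Q = Q, kappa = kappa, nu = nu,
                 p_value = min(max(p, P_FLOOR), 1),
                 method = method, model_id = model_id, gene_id = gene_id),
            class = "score_test_result")
}

#' @export
print.score_test_result <- function(x, ...) {
  cat("<score_test_result>",
      if (!is.na(x$gene_id)) paste0(" gene ", x$gene_id) else "",
      if (!is.na(x$model_id)) paste0(" [", x$model_id, "]") else "",
      "\n  Q = ", format(x$Q, digits = 5),
      ", kappa = ", format(x$kappa, digits = 5),
      ", nu = ", format(x$nu, digits = 5),
      "\n  p = ", format(x$p_value, digits = 5),
      "  (", x$method, ")\n", sep = "")
  invisible(x)
}

#' Satterthwaite p-value for the score statistic
#'
#' Matches the first two null moments of `Q` — mean `mu = tr(P0 K)/2` and
#' variance `v = tr((P0 K P0)^2)/2` — with a scaled chi-square:
#' `kappa = v / (2 mu)`, `nu = 2 mu^2 / v`, `p = P(chisq(nu) > Q / kappa)`.
#' Kernels that are constant on the residual space (e.g. an all-zero gene)
#' give `p = 1` with `method = "degenerate"`.
#'
#' @param fit A [fit_null()] object.
#' @param K `kernel_matrix` or square matrix.
#' @param Q Optional precomputed statistic; computed from `fit` and `K` if
#'   missing.
#' @return A `score_test_result`.
#' @export
satterthwaite_pvalue <- function(fit, K, Q = NULL) {
  stopifnot(inherits(fit, "null_fit"))
  if (is.null(Q)) Q <- score_statistic(fit, K)
  if (fit$degenerate)
    return(score_test_result(Q, NA_real_, NA_real_, 1, "degenerate"))
  mm <- null_moments(fit, K)
  if (moments_degenerate(mm$mu, mm$v, K))
    return(score_test_result(Q, NA_real_, NA_real_, 1, "degenerate"))
  kappa <- mm$v / (2 * mm$mu)
  nu <- 2 * mm$mu^2 / mm$v
  p <- stats::pchisq(Q / kappa, df = nu, lower.tail = FALSE)
  score_test_result(Q, kappa, nu, p, "satterthwaite")
}

#' Exact weighted-chi-square Monte Carlo p-value (oracle)
#'
#' Samples the exact null of `Q` — `sum_j lambda_j chisq(1)_j` with
#' `lambda_j` the eigenvalues of `P0 K P0 / 2` — and returns the tail
#' probability at the observed `Q`, with its Monte Carlo standard error as
#' attribute `"se"`. This is the validation oracle for
#' [satterthwaite_pvalue()]; it is not the production path.
#'
#' @inheritParams satterthwaite_pvalue
#' @param n_draws Number of Monte Carlo draws (>= 1e5).
#' @param seed Optional integer seed; the caller's RNG state is restored on
#'   exit.
#' @return The p-value, with attributes `se` and `n_draws`.
#' @export
exact_pvalue_mc <- function(fit, K, Q = NULL, n_draws = 1e5, seed = NULL) {
  stopifnot(inherits(fit, "null_fit"))
  if (n_draws < 1e5) stop("`n_draws` must be at least 1e5", call. = FALSE)
  if (is.null(Q)) Q <- score_statistic(fit, K)
  if (fit$degenerate) return(structure(1, se = 0, n_draws = n_draws))
  mm <- null_moments(fit, K)
  lam <- eigen(mm$B, symmetric = TRUE, only.values = TRUE)$values / 2
  lam <- lam[abs(lam) > 1e-12 * max(abs(lam), .Machine$double.eps)]
  if (!length(lam)) return(structure(1, se = 0, n_draws = n_draws))
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old_seed))
        assign(".Random.seed", old_seed, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  k <- length(lam)
  n_draws <- as.integer(n_draws)
  chunk <- max(1L, min(n_draws, as.integer(2e5)))
  exceed <- 0
  done <- 0L
  while (done < n_draws) {
    m <- min(chunk, n_draws - done)
    W <- matrix(stats::rchisq(k * m, df = 1), nrow = k)
    S <- drop(crossprod(lam, W))
    exceed <- exceed + sum(S >= Q)
    done <- done + m
  }
  p <- exceed / n_draws
  structure(p, se = sqrt(p * (1 - p) / n_draws), n_draws = n_draws)
}

#' BLUP of the kernel-machine random effect
#'
#' `h_hat = tau K (tau K + sigma2_hat I)^(-1) r`, the best linear unbiased
#' predictor of `h` at a given `tau`. Provided to exercise the
#' LSKM / mixed-model correspondence: it coincides with the kernel ridge
#' regression solution with penalty `sigma2_hat / tau`. Not used by the
#' test itself.
#'
#' @param fit A [fit_null()] object.
#' @param K `kernel_matrix` or square matrix.
#' @param tau Nonnegative variance component.
#' @return The n-vector `h_hat`.
#' @export
estimate_h_blup <- function(fit, K, tau) {
  stopifnot(inherits(fit, "null_fit"), tau >= 0)
  n <- fit$n
  if (tau == 0) return(numeric(n))
  V <- kernel_values(K)
  r <- fit$residuals
  M <- tau * V + diag(fit$sigma2_hat, n)
  sol <- tryCatch(solve(M, r), error = function(e) {
    jitter <- 1e-8 * mean(diag(M))
    if (isTRUE(getOption("kernelGxE.verbose", FALSE)))
      message("singular BLUP system; adding ridge jitter ", format(jitter))
    solve(M + diag(jitter, n), r)
  })
  drop(tau * (V %*% sol))
}

# Shared machinery for testing many phenotype replicates against one fixed
# design and kernel: the projection and the null moments are computed once,
# residuals for all replicates in a single qr.resid() call. This is what
# makes 2000-replicate calibration runs cheap (genotypes, covariates and
# hence X and K are fixed across replicates in the GAW17 design).

#' Score tests for a matrix of phenotype replicates
#'
#' Runs the Satterthwaite score test of [satterthwaite_pvalue()] for every
#' column of `Y` against a common design `X` and kernel `K`.
#'
#' @param Y n x m phenotype matrix (one column per replicate).
#' @param X Fixed-effect matrix (including any parametric genotype
#'   main-effect block).
#' @param K `kernel_matrix` or square matrix.
#' @return Data frame with one row per replicate: `replicate`, `Q`,
#'   `kappa`, `nu`, `p_value`, `method`.
#' @export
score_test_replicates <- function(Y, X, K) {
  Y <- as.matrix(Y)
  X <- drop_collinear(as.matrix(X))
  n <- nrow(Y)
  q <- ncol(X)
  if (nrow(X) != n) stop("`Y` and `X` have different sample counts",
                         call. = FALSE)
  if (n <= q) stop("need n > q", call. = FALSE)
  V <- kernel_values(K)
  qrx <- qr(X)
  R <- qr.resid(qrx, Y)
  sigma2 <- colSums(R^2) / (n - q)
  A <- V - qr.fitted(qrx, V)
  B <- A - t(qr.fitted(qrx, t(A)))
  B <- (B + t(B)) / 2
  mu <- sum(diag(B)) / 2
  v <- sum(B * B) / 2
  reps <- colnames(Y)
  if (is.null(reps)) reps <- as.character(seq_len(ncol(Y)))
  scale_y <- colMeans(Y^2) + .Machine$double.eps
  degen_fit <- sigma2 <= 1e-12 * scale_y
  Qs <- colSums(R * (V %*% R)) / (2 * pmax(sigma2, .Machine$double.xmin))
  if (moments_degenerate(mu, v, V)) {
    out <- data.frame(replicate = reps, Q = Qs, kappa = NA_real_,
                      nu = NA_real_, p_value = 1, method = "degenerate",
                      stringsAsFactors = FALSE)
    return(out)
  }
  kappa <- v / (2 * mu)
  nu <- 2 * mu^2 / v
  p <- stats::pchisq(Qs / kappa, df = nu, lower.tail = FALSE)
  p <- pmin(pmax(p, P_FLOOR), 1)
  method <- rep("satterthwaite", length(p))
  if (any(degen_fit)) {
    p[degen_fit] <- 1
    Qs[degen_fit] <- 0
    method[degen_fit] <- "degenerate"
  }
  data.frame(replicate = reps, Q = Qs, kappa = kappa, nu = nu,
             p_value = p, method = method, stringsAsFactors = FALSE)
}

#' Test one gene under one model formulation
#'
#' End-to-end composition: builds the design for the requested model, the
#' kernel on its kernel input, fits the null (appending the genotype
#' main-effect block to `X` for M11/M12) and returns the Satterthwaite
#' score-test result.
#'
#' @param y Phenotype vector.
#' @param model A [model_spec()].
#' @param G Gene genotype matrix.
#' @param covariates Covariate data frame (see [build_design()]).
#' @param G_wide Optional genome-wide genotypes for PC adjustment.
#' @param gene_id Optional label carried into the result.
#' @return A `score_test_result`.
#' @export
test_gene <- function(y, model, G, covariates, G_wide = NULL,
                      gene_id = NA_character_) {
  db <- build_design(model, G, covariates, G_wide = G_wide)
  X <- cbind(db$X, db$main_effect_block)
  fit <- fit_null(y, X)
  K <- build_kernel(model$kernel, db$kernel_input)
  res <- satterthwaite_pvalue(fit, K)
  res$model_id <- model$model_id
  res$gene_id <- gene_id
  res
}
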
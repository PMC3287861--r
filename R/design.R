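# Design assembly for the six model formulations.
#
# Fixed-effect matrix X always carries an intercept, Sex, standardized Age,
# the binary environment (Smoking) and any requested stratification PCs.
# The kernel input and the parametric genotype main-effect block vary by
# model:
#
#   M2   baseline             kernel on raw genotypes G
#   M10  burden baseline      kernel on the collapsed genotype c = rowSums(G)
#   M11  interaction-only     kernel on t = G * s, G moved to fixed effects
#   M12  interaction-only     kernel on t = c * s, c moved to fixed effects
#   M13  joint                kernel on [G | s | G * s]
#   M14  joint                kernel on [c | s | c * s]

MODEL_IDS <- c("M2", "M10", "M11", "M12", "M13", "M14")

#' Specify a model formulation
#'
#' @param model_id One of `"M2"`, `"M10"`, `"M11"`, `"M12"`, `"M13"`,
#'   `"M14"` (see the package overview for the mapping).
#' @param kernel A [kernel_spec()]. Defaults to the quadratic kernel for the
#'   joint models M13/M14 (the kernel used in the genome scans) and the
#'   linear kernel otherwise.
#' @param n_pcs Number of genotype principal components to append to the
#'   fixed effects (0 = no stratification adjustment).
#' @param environment_column Name of the binary exposure column in the
#'   covariate table. Default `"Smoking"`.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(model_id = MODEL_IDS, kernel = NULL, n_pcs = 0L,
                       environment_column = "Smoking") {
  model_id <- match.arg(model_id)
  if (is.null(kernel)) {
    kernel <- if (model_id %in% c("M13", "M14"))
      kernel_spec("polynomial", degree = 2L, offset = 0)
    else kernel_spec("linear")
  }
  stopifnot(inherits(kernel, "kernel_spec"))
  n_pcs <- as.integer(n_pcs)
  if (is.na(n_pcs) || n_pcs < 0L)
    stop("`n_pcs` must be a nonnegative integer", call. = FALSE)
  structure(list(model_id = model_id, kernel = kernel, n_pcs = n_pcs,
                 environment_column = environment_column),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", x$model_id, ", kernel = ", x$kernel$kind,
      ", n_pcs = ", x$n_pcs, ", environment = ", x$environment_column,
      "\n", sep = "")
  invisible(x)
}

#' Collapse a gene's genotypes to a burden score
#'
#' The combined genotype `c_i` is the per-individual sum of minor-allele
#' counts over the gene's SNPs, mitigating rare-variant sparsity.
#'
#' @param G Genotype matrix (samples x SNPs), entries in \{0, 1, 2\}.
#' @return Integer-valued vector of length n, in `[0, 2p]`.
#' @export
collapse_genotypes <- function(G) {
  G <- validate_genotype_matrix(G)
  rowSums(G)
}

#' Gene-environment interaction product terms
#'
#' Multiplies every genotype column (raw or collapsed) by the binary
#' exposure, so non-exposed samples contribute all-zero rows.
#'
#' @param Gc Genotype matrix (n x p) or collapsed genotype (n-vector or
#'   n x 1 matrix).
#' @param s Binary exposure vector in \{0, 1\}.
#' @return Matrix of the same width as `Gc`.
#' @export
interaction_terms <- function(Gc, s) {
  if (!is.matrix(Gc)) Gc <- matrix(Gc, ncol = 1L,
                                   dimnames = list(names(Gc), "burden"))
  check_binary(s, nrow(Gc), "exposure")
  Gc * s
}

check_binary <- function(s, n, what) {
  if (!is.numeric(s) || length(s) != n || anyNA(s) || !all(s %in% c(0, 1)))
    stop("`", what, "` must be a binary (0/1) vector of length ", n,
         "; continuous exposures are not supported", call. = FALSE)
  invisible(s)
}

#' Augmented kernel input for the joint models
#'
#' Column-concatenates genotypes (raw or collapsed), exposure and the
#' interaction terms, in that order; this is the matrix the quadratic kernel
#' of the joint models M13/M14 is built on.
#'
#' @param Gc Genotype matrix or collapsed genotype.
#' @param s Binary exposure.
#' @param T Interaction terms from [interaction_terms()].
#' @return Matrix `[Gc | s | T]`.
#' @export
joint_kernel_input <- function(Gc, s, T) {
  if (!is.matrix(Gc)) Gc <- matrix(Gc, ncol = 1L, dimnames = list(NULL, "burden"))
  if (!is.matrix(T)) T <- matrix(T, ncol = 1L)
  if (nrow(Gc) != length(s) || nrow(T) != length(s) || ncol(T) != ncol(Gc))
    stop("dimension mismatch between genotypes, exposure and interaction terms",
         call. = FALSE)
  out <- cbind(Gc, s = s, T)
  cn <- colnames(Gc)
  if (is.null(cn)) cn <- paste0("g", seq_len(ncol(Gc)))
  colnames(out) <- c(cn, "s", paste0(cn, ":s"))
  rownames(out) <- rownames(Gc)
  out
}

#' Principal components of a genome-wide genotype matrix
#'
#' Columns are centered and (by default) scaled by their sample standard
#' deviation, skipping zero-variance SNPs; scores are ordered by decreasing
#' eigenvalue, with the sign of each component fixed by forcing its
#' largest-magnitude SNP loading positive. If `k` exceeds the matrix rank
#' the trailing components are zero and flagged in the
#' `"zero_variance"` attribute.
#'
#' @param G_wide Genotype matrix across all available SNPs (not one gene).
#' @param k Number of components (0 returns an n x 0 matrix).
#' @param scale. Scale columns to unit variance before the decomposition.
#' @return n x k score matrix with columns `PC1..PCk`.
#' @export
compute_pcs <- function(G_wide, k, scale. = TRUE) {
  G_wide <- as.matrix(G_wide)
  n <- nrow(G_wide)
  k <- as.integer(k)
  if (k < 0L) stop("`k` must be >= 0", call. = FALSE)
  if (k == 0L) {
    out <- matrix(numeric(0), nrow = n, ncol = 0L)
    rownames(out) <- rownames(G_wide)
    return(out)
  }
  if (k > min(n, ncol(G_wide)))
    stop("`k` cannot exceed min(n, P)", call. = FALSE)
  Z <- scale(G_wide, center = TRUE, scale = FALSE)
  if (scale.) {
    sds <- apply(Z, 2, stats::sd)
    sds[sds == 0 | !is.finite(sds)] <- 1   # zero-variance SNPs stay zero
    Z <- sweep(Z, 2, sds, "/")
  }
  sv <- svd(Z, nu = k, nv = k)
  d <- sv$d[seq_len(k)]
  scores <- sv$u %*% diag(d, nrow = k)
  # deterministic sign: largest-|loading| positive per component
  for (j in seq_len(k)) {
    i_star <- which.max(abs(sv$v[, j]))
    if (sv$v[i_star, j] < 0) scores[, j] <- -scores[, j]
  }
  tol <- max(sv$d) * max(dim(Z)) * .Machine$double.eps
  zero_var <- which(d <= tol)
  if (length(zero_var)) scores[, zero_var] <- 0
  dimnames(scores) <- list(rownames(G_wide), paste0("PC", seq_len(k)))
  attr(scores, "zero_variance") <- zero_var
  attr(scores, "sdev") <- d / sqrt(max(1, n - 1))
  scores
}

# Greedy left-to-right pruning: keep each column only if it increases the
# rank, so "later" collinear columns are the ones dropped (deterministic).
drop_collinear <- function(X, tol = 1e-7) {
  X <- as.matrix(X)
  qrx <- qr(X, tol = tol)
  if (qrx$rank == ncol(X)) return(X)
  keep <- integer(0)
  for (j in seq_len(ncol(X))) {
    cand <- c(keep, j)
    if (qr(X[, cand, drop = FALSE], tol = tol)$rank == length(cand))
      keep <- cand
  }
  dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
  if (isTRUE(getOption("kernelGxE.verbose", FALSE)))
    message("dropping collinear column(s): ",
            paste(dropped, collapse = ", "))
  X[, keep, drop = FALSE]
}

covariate_ids <- function(covariates) {
  if ("sample_id" %in% colnames(covariates))
    as.character(covariates[["sample_id"]])
  else rownames(covariates)
}

#' Assemble the design for one gene and model
#'
#' Builds the fixed-effect matrix `X` (intercept, Sex, z-scored Age, the
#' binary environment, optional PCs), the kernel input matrix, and — for the
#' interaction-only models M11/M12 — the genotype main-effect block that is
#' estimated parametrically under the null.
#'
#' @param model A [model_spec()].
#' @param G Genotype matrix for the gene (samples x SNPs), rownames = sample
#'   IDs.
#' @param covariates Data frame with columns `sample_id`, `Sex`, `Age` and
#'   the environment column (plus optional `PC1..` columns used when
#'   `G_wide` is not supplied).
#' @param G_wide Optional genome-wide genotype matrix used to compute
#'   stratification PCs when `model$n_pcs > 0`.
#' @return A list of class `design_bundle` with elements `X`,
#'   `kernel_input`, `main_effect_block`, `column_names` and `model`.
#' @export
build_design <- function(model, G, covariates, G_wide = NULL) {
  stopifnot(inherits(model, "model_spec"))
  G <- validate_genotype_matrix(G)
  ids <- rownames(G)
  cov_ids <- covariate_ids(covariates)
  n <- nrow(G)
  if (nrow(covariates) != n)
    stop("genotype and covariate tables have different sample counts",
         call. = FALSE)
  if (!is.null(ids) && !is.null(cov_ids) && !all(ids == cov_ids))
    stop("sample IDs of genotypes and covariates do not match (same order required)",
         call. = FALSE)
  env <- model$environment_column
  for (nm in c("Sex", "Age", env))
    if (!nm %in% colnames(covariates))
      stop("covariate table lacks required column `", nm, "`", call. = FALSE)
  s <- as.numeric(covariates[[env]])
  check_binary(s, n, env)
  age <- as.numeric(covariates[["Age"]])
  age_sd <- stats::sd(age)
  age_z <- if (is.finite(age_sd) && age_sd > 0) (age - mean(age)) / age_sd
           else rep(0, n)

  X <- cbind(`(Intercept)` = 1, Sex = as.numeric(covariates[["Sex"]]),
             Age = age_z)
  X <- cbind(X, s)
  colnames(X)[ncol(X)] <- env

  if (model$n_pcs > 0L) {
    if (!is.null(G_wide)) {
      if (!is.null(rownames(G_wide)) && !is.null(ids) &&
          !all(rownames(G_wide) == ids))
        stop("sample IDs of G_wide do not match", call. = FALSE)
      pcs <- compute_pcs(G_wide, min(model$n_pcs, nrow(G_wide) - 1L,
                                     ncol(G_wide)))
    } else {
      pc_cols <- paste0("PC", seq_len(model$n_pcs))
      if (!all(pc_cols %in% colnames(covariates)))
        stop("`n_pcs` > 0 but neither G_wide nor PC columns supplied",
             call. = FALSE)
      pcs <- as.matrix(covariates[, pc_cols, drop = FALSE])
    }
    X <- cbind(X, pcs)
  }
  if (ncol(X) + 1L > n)
    stop("too many fixed effects for the sample size (n_pcs too large)",
         call. = FALSE)

  cvec <- rowSums(G)
  cmat <- matrix(cvec, ncol = 1L, dimnames = list(ids, "burden"))
  mid <- model$model_id
  bundle <- switch(mid,
    M2 = list(kernel_input = G, main_effect_block = NULL),
    M10 = list(kernel_input = cmat, main_effect_block = NULL),
    M11 = list(kernel_input = interaction_terms(G, s),
               main_effect_block = G),
    M12 = list(kernel_input = interaction_terms(cmat, s),
               main_effect_block = cmat),
    M13 = list(kernel_input = joint_kernel_input(G, s,
                                                 interaction_terms(G, s)),
               main_effect_block = NULL),
    M14 = list(kernel_input = joint_kernel_input(cmat, s,
                                                 interaction_terms(cmat, s)),
               main_effect_block = NULL))

  X <- drop_collinear(X)
  structure(list(X = X,
                 kernel_input = bundle$kernel_input,
                 main_effect_block = bundle$main_effect_block,
                 column_names = list(
                   X = colnames(X),
                   kernel_input = colnames(bundle$kernel_input),
                   main_effect_block = colnames(bundle$main_effect_block)),
                 model = model),
            class = "design_bundle")
}

#' @export
print.design_bundle <- function(x, ...) {
  cat("<design_bundle> ", x$model$model_id,
      ": X ", nrow(x$X), "x", ncol(x$X),
      ", kernel input width ", ncol(x$kernel_input),
      if (!is.null(x$main_effect_block))
        paste0(", main-effect block width ", ncol(x$main_effect_block))
      else "",
      "\n", sep = "")
  invisible(x)
}
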
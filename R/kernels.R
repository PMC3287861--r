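# Kernel construction over SNP-set (or augmented) input matrices.
#
# Every constructor returns a `kernel_matrix`: the n x n similarity values,
# the `kernel_spec` that produced them, and an opaque hash of the input used
# for per-kernel caching downstream. Matrices are symmetrized after
# construction so that downstream eigen/trace computations can assume exact
# symmetry.

#' Describe a kernel
#'
#' A `kernel_spec` names one of the four supported kernel families and its
#' parameters. The linear kernel is the polynomial kernel with `degree = 1`,
#' `offset = 0`, and is normalized to those values on construction so the two
#' specifications produce identical matrices.
#'
#' @param kind One of `"linear"`, `"polynomial"`, `"gaussian"`, `"iis"`.
#' @param degree Polynomial degree `d` (>= 1). Ignored unless
#'   `kind = "polynomial"`. Default 2 (quadratic), the kernel used for the
#'   genome scans.
#' @param offset Nonnegative constant term `c` of the polynomial kernel
#'   `(z'z + c)^d`. Default 0 (homogeneous kernel).
#' @param bandwidth Bandwidth `rho > 0` of the Gaussian kernel
#'   `exp(-||z - z'||^2 / rho)`. `NULL` means "number of input columns",
#'   resolved when the kernel is built.
#' @return An object of class `kernel_spec`.
#' @seealso [build_kernel()]
#' @export
kernel_spec <- function(kind = c("linear", "polynomial", "gaussian", "iis"),
                        degree = 2L, offset = 0, bandwidth = NULL) {
  kind <- match.arg(kind)
  degree <- as.integer(degree)
  if (is.na(degree) || degree < 1L)
    stop("`degree` must be a positive integer", call. = FALSE)
  if (!is.numeric(offset) || length(offset) != 1L || !is.finite(offset) ||
      offset < 0)
    stop("`offset` must be a nonnegative number", call. = FALSE)
  if (kind == "linear") {
    degree <- 1L
    offset <- 0
  }
  if (!is.null(bandwidth)) {
    if (!is.numeric(bandwidth) || length(bandwidth) != 1L ||
        !is.finite(bandwidth) || bandwidth <= 0)
      stop("`bandwidth` must be a positive number", call. = FALSE)
  }
  structure(list(kind = kind, degree = degree, offset = offset,
                 bandwidth = bandwidth),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  extra <- switch(x$kind,
    polynomial = sprintf(" (degree = %d, offset = %g)", x$degree, x$offset),
    gaussian = sprintf(" (bandwidth = %s)",
                       if (is.null(x$bandwidth)) "ncol(Z)" else
                         format(x$bandwidth)),
    "")
  cat("<kernel_spec> ", x$kind, extra, "\n", sep = "")
  invisible(x)
}

# Cheap deterministic identifier for an input matrix; only used as a cache
# key, not for cryptographic purposes.
input_hash <- function(Z) {
  Z <- as.matrix(Z)
  paste0(nrow(Z), "x", ncol(Z), "-",
         format(sum(Z), digits = 17), "-",
         format(sum(Z * seq_along(Z)), digits = 17))
}

validate_kernel_input <- function(Z, min_rows = 2L) {
  if (is.data.frame(Z)) Z <- as.matrix(Z)
  if (!is.matrix(Z) || !is.numeric(Z))
    stop("kernel input must be a numeric matrix", call. = FALSE)
  if (nrow(Z) < min_rows || ncol(Z) < 1L)
    stop("kernel input must have at least ", min_rows,
         " rows and 1 column", call. = FALSE)
  if (!all(is.finite(Z)))
    stop("kernel input contains non-finite values", call. = FALSE)
  Z
}

validate_genotype_matrix <- function(G, impute_missing = FALSE) {
  if (is.data.frame(G)) G <- as.matrix(G)
  if (!is.matrix(G) || !is.numeric(G))
    stop("genotypes must be a numeric matrix", call. = FALSE)
  if (anyNA(G)) {
    if (!impute_missing)
      stop("genotype matrix contains missing values; set ",
           "`impute_missing = TRUE` to impute to the per-SNP mean",
           call. = FALSE)
    for (j in seq_len(ncol(G))) {
      miss <- is.na(G[, j])
      if (any(miss)) {
        mj <- mean(G[!miss, j])
        if (!is.finite(mj)) mj <- 0
        G[miss, j] <- mj
      }
    }
  }
  ok <- G >= 0 & G <= 2
  if (!all(ok))
    stop("genotype entries must be minor-allele counts in {0, 1, 2}",
         call. = FALSE)
  if (any(abs(G - round(G)) > 1e-8) && !impute_missing)
    stop("genotype entries must be integers 0, 1 or 2", call. = FALSE)
  mono <- apply(G, 2, function(x) all(x == x[1]))
  if (any(mono) && isTRUE(getOption("kernelGxE.verbose", FALSE)))
    message(sum(mono), " monomorphic SNP column(s) retained")
  G
}

new_kernel_matrix <- function(values, spec, Z) {
  values <- (values + t(values)) / 2   # enforce exact symmetry
  ids <- rownames(Z)
  if (!is.null(ids)) dimnames(values) <- list(ids, ids)
  structure(list(values = values, spec = spec, input_hash = input_hash(Z)),
            class = "kernel_matrix")
}

#' @export
as.matrix.kernel_matrix <- function(x, ...) x$values

#' @export
print.kernel_matrix <- function(x, ...) {
  cat("<kernel_matrix> ", nrow(x$values), " x ", ncol(x$values),
      ", kind = ", x$spec$kind, "\n", sep = "")
  invisible(x)
}

# Accept either a kernel_matrix or a plain symmetric matrix.
kernel_values <- function(K) {
  if (inherits(K, "kernel_matrix")) return(K$values)
  if (is.matrix(K) && nrow(K) == ncol(K)) return((K + t(K)) / 2)
  stop("`K` must be a kernel_matrix or a square numeric matrix",
       call. = FALSE)
}

#' Polynomial kernel
#'
#' Entry (i, i') is `(z_i . z_i' + offset)^degree`. With `degree = 1`,
#' `offset = 0` this is the linear kernel `Z Z'`; with `degree = 2` the
#' quadratic kernel whose implicit feature space is given by
#' [quadratic_feature_map()].
#'
#' @param Z Numeric input matrix, samples in rows (n >= 2).
#' @param degree Positive integer degree `d`.
#' @param offset Nonnegative constant term.
#' @return A `kernel_matrix`.
#' @examples
#' polynomial_kernel(rbind(c(1, 2), c(2, 0)), degree = 2)
#' @export
polynomial_kernel <- function(Z, degree = 2L, offset = 0) {
  spec <- kernel_spec("polynomial", degree = degree, offset = offset)
  Z <- validate_kernel_input(Z)
  K <- (tcrossprod(Z) + spec$offset)^spec$degree
  new_kernel_matrix(K, spec, Z)
}

#' Explicit feature map of the quadratic kernel
#'
#' Returns `phi(g)` such that `phi(a) . phi(b) = (a . b + offset)^2` exactly:
#' squared coordinates plus sqrt(2)-scaled pairwise products (row-major over
#' pairs i <= j), and, when `offset > 0`, the additional `sqrt(2 * offset) * g`
#' block and the constant `offset`. This is the "kernel trick" made explicit
#' and serves as the exactness oracle for [polynomial_kernel()] at degree 2.
#'
#' @param g Numeric vector of length m >= 1.
#' @param offset Nonnegative constant term of the kernel.
#' @return Numeric vector of length `m(m+1)/2` (plus `m + 1` if `offset > 0`).
#' @examples
#' quadratic_feature_map(c(1, 2))  # (1, 2*sqrt(2), 4)
#' @export
quadratic_feature_map <- function(g, offset = 0) {
  if (!is.numeric(g) || length(g) < 1L || !all(is.finite(g)))
    stop("`g` must be a finite numeric vector", call. = FALSE)
  if (offset < 0) stop("`offset` must be >= 0", call. = FALSE)
  m <- length(g)
  out <- numeric(m * (m + 1L) / 2L)
  pos <- 1L
  s2 <- sqrt(2)
  for (i in seq_len(m)) {
    for (j in i:m) {
      out[pos] <- if (i == j) g[i]^2 else s2 * g[i] * g[j]
      pos <- pos + 1L
    }
  }
  if (offset > 0) out <- c(out, sqrt(2 * offset) * g, offset)
  out
}

#' Gaussian (radial basis) kernel
#'
#' Entry (i, i') is `exp(-||z_i - z_i'||^2 / bandwidth)`; the diagonal is
#' exactly 1. The default bandwidth is the number of input columns, which
#' scales the squared distance by the input dimension.
#'
#' @inheritParams polynomial_kernel
#' @param bandwidth Positive bandwidth `rho`; default `ncol(Z)`.
#' @return A `kernel_matrix` with entries in (0, 1] and unit diagonal.
#' @export
gaussian_kernel <- function(Z, bandwidth = NULL) {
  Z <- validate_kernel_input(Z)
  if (is.null(bandwidth)) bandwidth <- ncol(Z)
  spec <- kernel_spec("gaussian", bandwidth = bandwidth)
  D2 <- as.matrix(stats::dist(Z))^2
  K <- exp(-D2 / bandwidth)
  diag(K) <- 1
  new_kernel_matrix(K, spec, Z)
}

#' Identity-in-state (IIS) similarity kernel
#'
#' Allele-sharing similarity across a SNP set: at each SNP the number of
#' alleles identical in state between two genotypes a, b in {0, 1, 2} is
#' `2 - |a - b|`; the kernel entry sums these over the p SNPs and divides by
#' `2p` (so entries lie in `[0, 1]` with unit diagonal) or, optionally, by
#' `p`.
#'
#' @param G Genotype matrix of minor-allele counts in \{0, 1, 2\}
#'   (samples x SNPs).
#' @param normalization `"2p"` (default, entries in `[0, 1]`) or `"p"`.
#' @param impute_missing If `TRUE`, missing genotypes are imputed to the
#'   per-SNP mean rounded to the nearest integer; the default is to reject
#'   missing data.
#' @return A `kernel_matrix`.
#' @examples
#' iis_kernel(rbind(a = c(0, 1, 2), b = c(1, 1, 0)))
#' @export
iis_kernel <- function(G, normalization = c("2p", "p"),
                       impute_missing = FALSE) {
  normalization <- match.arg(normalization)
  G <- validate_genotype_matrix(G, impute_missing = impute_missing)
  if (impute_missing) G <- round(G)
  G <- validate_kernel_input(G)
  p <- ncol(G)
  D <- as.matrix(stats::dist(G, method = "manhattan"))
  shared <- 2 * p - D
  K <- shared / if (normalization == "2p") (2 * p) else p
  spec <- kernel_spec("iis")
  new_kernel_matrix(K, spec, G)
}

#' Build the kernel a spec describes
#'
#' @param spec A [kernel_spec()].
#' @param Z Input matrix (genotypes for `"iis"`, any numeric matrix
#'   otherwise).
#' @param ... Passed on to the underlying constructor (e.g.
#'   `impute_missing` for the IIS kernel).
#' @return A `kernel_matrix`.
#' @export
build_kernel <- function(spec, Z, ...) {
  stopifnot(inherits(spec, "kernel_spec"))
  switch(spec$kind,
    linear = polynomial_kernel(Z, degree = 1L, offset = 0),
    polynomial = polynomial_kernel(Z, degree = spec$degree,
                                   offset = spec$offset),
    gaussian = gaussian_kernel(Z, bandwidth = spec$bandwidth),
    iis = iis_kernel(Z, ...))
}

#' Check a kernel matrix is positive semidefinite up to tolerance
#'
#' @param K `kernel_matrix` or square matrix.
#' @param tol Relative tolerance: the smallest eigenvalue must be
#'   `>= -tol * largest`.
#' @return `TRUE`/`FALSE`.
#' @export
is_psd <- function(K, tol = 1e-8) {
  V <- kernel_values(K)
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  lmax <- max(abs(ev), .Machine$double.eps)
  min(ev) >= -tol * lmax
}

#' Write / read a kernel matrix as square TSV (sample IDs as header row and
#' first column); a debugging interchange format.
#'
#' @param K `kernel_matrix` or square matrix.
#' @param path Output file.
#' @export
write_kernel_tsv <- function(K, path) {
  V <- kernel_values(K)
  ids <- rownames(V)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(V)))
  df <- data.frame(sample_id = ids, V, check.names = FALSE)
  colnames(df) <- c("sample_id", ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kernel_tsv
#' @export
read_kernel_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  ids <- as.character(df[[1L]])
  V <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(V) <- list(ids, ids)
  V
}
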
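# Per-gene, per-replicate scan driver plus Q-Q and power summaries.

#' Scan genes x models x replicates
#'
#' Applies the variance-component score test to every requested gene, model
#' and phenotype replicate of a replicate set. The design and kernel for a
#' (gene, model) pair are shared across replicates (genotypes are fixed in
#' the GAW17 layout), so the projection and null moments are computed once
#' per pair. Per-gene failures are recorded (`p_value = NA`,
#' `method = "error"`) and the scan continues.
#'
#' @param rs A `replicate_set` (see [simulate_replicates()] /
#'   [read_fixture()]).
#' @param models A [model_spec()] or list of them.
#' @param genes Gene IDs to test; default all genes in the gene map.
#' @param replicates Indices or names of phenotype columns; default all.
#' @return Data frame of class `scan_result`: `gene_id`, `model_id`,
#'   `replicate`, `Q`, `kappa`, `nu`, `p_value`, `method`; provenance
#'   (seed, models) in attributes.
#' @export
run_scan <- function(rs, models, genes = NULL, replicates = NULL) {
  stopifnot(inherits(rs, "replicate_set"))
  if (inherits(models, "model_spec")) models <- list(models)
  if (is.null(genes)) genes <- unique(rs$gene_map$gene_id)
  Y <- rs$Y
  if (!is.null(replicates)) Y <- Y[, replicates, drop = FALSE]
  out <- vector("list", length(models) * length(genes))
  i <- 0L
  for (model in models) {
    for (gene in genes) {
      i <- i + 1L
      snps <- rs$gene_map$snp_id[rs$gene_map$gene_id == gene]
      if (!length(snps)) stop("gene `", gene, "` not in gene map",
                              call. = FALSE)
      tab <- tryCatch({
        G <- rs$G_wide[, snps, drop = FALSE]
        db <- build_design(model, G, rs$covariates, G_wide = rs$G_wide)
        K <- build_kernel(model$kernel, db$kernel_input)
        score_test_replicates(Y, cbind(db$X, db$main_effect_block), K)
      }, error = function(e) {
        warning("gene ", gene, " / ", model$model_id, " failed: ",
                conditionMessage(e), call. = FALSE)
        data.frame(replicate = colnames(Y), Q = NA_real_,
                   kappa = NA_real_, nu = NA_real_, p_value = NA_real_,
                   method = "error", stringsAsFactors = FALSE)
      })
      tab <- cbind(gene_id = gene, model_id = model$model_id, tab,
                   stringsAsFactors = FALSE)
      out[[i]] <- tab
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "seed") <- rs$config$seed
  attr(res, "models") <- vapply(models, `[[`, "", "model_id")
  attr(res, "version") <- as.character(utils::packageVersion("kernelGxE"))
  class(res) <- c("scan_result", class(res))
  res
}

#' Q-Q data with a pointwise 95% null band
#'
#' For m p-values, the i-th smallest observed p is paired with the
#' expected value `-log10(median of Beta(i, m - i + 1))` (the median of the
#' i-th uniform order statistic) and a pointwise 95% band from the 0.025
#' and 0.975 Beta quantiles. Rank 1 is the most significant point.
#'
#' @param pvalues Vector of p-values in (0, 1]; zeros are clipped to 1e-300
#'   with a warning.
#' @return Data frame: `rank`, `observed`, `expected`, `lower`, `upper`
#'   (all on the -log10 scale).
#' @export
qq_data <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (!length(p) || anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (any(p == 0)) {
    warning("p-values of 0 clipped to 1e-300")
    p[p == 0] <- 1e-300
  }
  m <- length(p)
  i <- seq_len(m)
  data.frame(
    rank = i,
    observed = -log10(sort(p)),
    expected = -log10(stats::qbeta(0.5, i, m - i + 1)),
    lower = -log10(stats::qbeta(0.975, i, m - i + 1)),
    upper = -log10(stats::qbeta(0.025, i, m - i + 1)))
}

#' Empirical power / size table
#'
#' Per (gene, model): the fraction of replicates with `p <= alpha`, with
#' its binomial Monte Carlo standard error.
#'
#' @param scan_result Output of [run_scan()] (or any data frame with
#'   `gene_id`, `model_id`, `p_value`).
#' @param alpha Significance level in (0, 1).
#' @return Data frame: `gene_id`, `model_id`, `n_replicates`, `power`,
#'   `mc_se`.
#' @export
empirical_power <- function(scan_result, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)",
                                     call. = FALSE)
  sr <- as.data.frame(scan_result)
  groups <- unique(sr[, c("gene_id", "model_id")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    sel <- sr$gene_id == groups$gene_id[i] &
      sr$model_id == groups$model_id[i] & !is.na(sr$p_value)
    m <- sum(sel)
    pw <- mean(sr$p_value[sel] <= alpha)
    data.frame(gene_id = groups$gene_id[i],
               model_id = groups$model_id[i],
               n_replicates = m, power = pw,
               mc_se = sqrt(pw * (1 - pw) / max(m, 1)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a scan result as TSV
#'
#' @param scan_result Output of [run_scan()].
#' @param path Output file.
#' @export
write_scan_tsv <- function(scan_result, path) {
  utils::write.table(as.data.frame(scan_result), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
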
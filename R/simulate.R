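# GAW17-like synthetic data.
#
# The generator emulates the structure of the GAW17 unrelated-individuals
# exome set as used for the quantitative trait Q1: ~700 unrelated samples,
# genes made mostly of rare variants, latent subpopulations (Balding-
# Nichols allele-frequency divergence plus a subpopulation trait shift, so
# stratification confounds naive joint analyses), covariates Sex / Age /
# Smoking, and many phenotype replicates drawn on a single fixed genotype
# draw. Exactly one gene carries a gene-by-smoking interaction; one gene a
# large marginal effect; the rest are noise.

#' Describe one simulated gene
#'
#' @param gene_id Gene label.
#' @param n_snps Number of SNPs in the gene.
#' @param rare_fraction Fraction of the gene's SNPs drawn from the rare MAF
#'   range.
#' @param rare_maf_range,common_maf_range MAF ranges (uniform draws),
#'   within (0, 0.5].
#' @param beta_main Main effect per unit of the collapsed genotype `c`.
#' @param beta_gxe Interaction effect per unit of `Smoking * c`.
#' @return A list describing the gene.
#' @export
sim_gene <- function(gene_id, n_snps = 10L, rare_fraction = 0.8,
                     rare_maf_range = c(0.005, 0.02),
                     common_maf_range = c(0.05, 0.2),
                     beta_main = 0, beta_gxe = 0) {
  check_maf_range <- function(r, nm) {
    if (length(r) != 2L || any(r <= 0) || any(r > 0.5) || r[1] > r[2])
      stop("`", nm, "` must be an increasing range within (0, 0.5]",
           call. = FALSE)
  }
  check_maf_range(rare_maf_range, "rare_maf_range")
  check_maf_range(common_maf_range, "common_maf_range")
  if (rare_fraction < 0 || rare_fraction > 1)
    stop("`rare_fraction` must be in [0, 1]", call. = FALSE)
  if (n_snps < 1L) stop("`n_snps` must be >= 1", call. = FALSE)
  list(gene_id = as.character(gene_id), n_snps = as.integer(n_snps),
       rare_fraction = rare_fraction, rare_maf_range = rare_maf_range,
       common_maf_range = common_maf_range,
       beta_main = beta_main, beta_gxe = beta_gxe)
}

#' Default gene set: one interaction gene, one large-marginal-effect gene,
#' two noise genes
#'
#' Effect sizes were fixed a priori from a noncentrality calculation (see
#' the methods vignette) so that the interaction test has usable power
#' (0.3-0.9) at n = 697 with 200 replicates; `scripts/calibrate.R`
#' reproduces the calibration.
#'
#' @param beta_gxe Interaction effect at the `GENE_GXE` gene.
#' @param beta_main Main effect at the `GENE_MAIN` gene.
#' @return List of [sim_gene()] descriptions.
#' @export
default_gene_set <- function(beta_gxe = 0.35, beta_main = 0.4) {
  list(
    sim_gene("GENE_GXE", beta_gxe = beta_gxe),
    sim_gene("GENE_MAIN", beta_main = beta_main),
    sim_gene("NOISE_A"),
    sim_gene("NOISE_B"))
}

#' Configuration of the synthetic experiment
#'
#' Defaults state the emulated world: 697 unrelated individuals, two latent
#' subpopulations with Balding-Nichols divergence 0.05 and a trait shift of
#' 0.5 residual SD between them (population structure is present in GAW17
#' though not planned), Sex ~ Bernoulli(0.5), Age ~ N(49, 12),
#' Smoking ~ Bernoulli(0.3), residual SD 1, and 200 phenotype replicates on
#' one fixed genotype draw.
#'
#' @param n_samples Number of unrelated individuals.
#' @param genes List of [sim_gene()] descriptions; at most one may have
#'   `beta_gxe != 0`.
#' @param n_background_snps Extra polymorphic SNPs (outside any gene) that
#'   feed the stratification PCs.
#' @param background_rare_fraction,background_rare_maf_range,background_common_maf_range
#'   MAF spectrum of the background SNPs.
#' @param n_subpops Number of latent subpopulations.
#' @param divergence Balding-Nichols Fst-like divergence of subpopulation
#'   allele frequencies from the ancestral MAF (0 = panmictic).
#' @param subpop_trait_shift Difference in trait mean per unit of centered
#'   subpopulation label (residual-SD units).
#' @param beta_sex,beta_age,beta_smoking Covariate effects (Age effect per
#'   SD of age).
#' @param smoking_prevalence P(Smoking = 1).
#' @param sigma_e Residual SD.
#' @param n_replicates Number of phenotype replicates (>= 1).
#' @param seed Integer seed; genotypes and covariates are drawn once per
#'   seed, phenotype replicates from a derived seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 697L, genes = default_gene_set(),
                       n_background_snps = 1000L,
                       background_rare_fraction = 0.5,
                       background_rare_maf_range = c(0.005, 0.02),
                       background_common_maf_range = c(0.05, 0.4),
                       n_subpops = 2L, divergence = 0.05,
                       subpop_trait_shift = 0.5,
                       beta_sex = 0.25, beta_age = 0.1, beta_smoking = 0.5,
                       smoking_prevalence = 0.3,
                       sigma_e = 1, n_replicates = 200L, seed = 17L) {
  if (n_samples < 10L) stop("`n_samples` too small", call. = FALSE)
  if (n_replicates < 1L) stop("`n_replicates` must be >= 1", call. = FALSE)
  if (n_subpops < 1L) stop("`n_subpops` must be >= 1", call. = FALSE)
  if (divergence < 0 || divergence >= 1)
    stop("`divergence` must be in [0, 1)", call. = FALSE)
  if (sigma_e <= 0) stop("`sigma_e` must be > 0", call. = FALSE)
  gene_ids <- vapply(genes, `[[`, "", "gene_id")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids", call. = FALSE)
  n_gxe <- sum(vapply(genes, function(g) g$beta_gxe != 0, logical(1)))
  if (n_gxe > 1L)
    stop("at most one gene may carry a gene-environment interaction ",
         "(the GAW17 design simulates exactly one)", call. = FALSE)
  structure(list(n_samples = as.integer(n_samples), genes = genes,
                 n_background_snps = as.integer(n_background_snps),
                 background_rare_fraction = background_rare_fraction,
                 background_rare_maf_range = background_rare_maf_range,
                 background_common_maf_range = background_common_maf_range,
                 n_subpops = as.integer(n_subpops), divergence = divergence,
                 subpop_trait_shift = subpop_trait_shift,
                 beta_sex = beta_sex, beta_age = beta_age,
                 beta_smoking = beta_smoking,
                 smoking_prevalence = smoking_prevalence,
                 sigma_e = sigma_e, n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> n = ", x$n_samples, ", ", length(x$genes), " genes + ",
      x$n_background_snps, " background SNPs, ", x$n_subpops,
      " subpops (divergence ", x$divergence, "), ", x$n_replicates,
      " replicates, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

draw_mafs <- function(k, rare_fraction, rare_range, common_range) {
  is_rare <- stats::runif(k) < rare_fraction
  maf <- numeric(k)
  maf[is_rare] <- stats::runif(sum(is_rare), rare_range[1], rare_range[2])
  maf[!is_rare] <- stats::runif(sum(!is_rare), common_range[1],
                                common_range[2])
  maf
}

#' Simulate genotypes with latent population structure
#'
#' Per SNP, an ancestral MAF is drawn from the configured spectrum;
#' subpopulation frequencies follow a Balding-Nichols
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` draw around it (identical to the
#' ancestral value when `divergence = 0`); genotypes are
#' `Binomial(2, subpop frequency)`. Counts are re-oriented so the recorded
#' allele is the minor allele in the pooled sample.
#'
#' @param config A [sim_config()].
#' @return List with `G_wide` (samples x all SNPs), `gene_map`
#'   (`gene_id`, `snp_id`; gene SNPs only) and `subpop` (integer labels).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  ids <- sprintf("S%04d", seq_len(n))
  subpop <- sort(rep_len(seq_len(config$n_subpops), n))

  snp_ids <- character(0)
  gene_of <- character(0)
  mafs <- numeric(0)
  for (g in config$genes) {
    m <- draw_mafs(g$n_snps, g$rare_fraction, g$rare_maf_range,
                   g$common_maf_range)
    snp_ids <- c(snp_ids, sprintf("%s_s%02d", g$gene_id,
                                  seq_len(g$n_snps)))
    gene_of <- c(gene_of, rep(g$gene_id, g$n_snps))
    mafs <- c(mafs, m)
  }
  if (config$n_background_snps > 0L) {
    m <- draw_mafs(config$n_background_snps,
                   config$background_rare_fraction,
                   config$background_rare_maf_range,
                   config$background_common_maf_range)
    snp_ids <- c(snp_ids, sprintf("BG_s%04d",
                                  seq_len(config$n_background_snps)))
    gene_of <- c(gene_of, rep(NA_character_, config$n_background_snps))
    mafs <- c(mafs, m)
  }
  P <- length(snp_ids)

  F <- config$divergence
  freqs <- matrix(mafs, nrow = P, ncol = config$n_subpops)
  if (F > 0 && config$n_subpops > 1L) {
    a <- mafs * (1 - F) / F
    b <- (1 - mafs) * (1 - F) / F
    for (k in seq_len(config$n_subpops))
      freqs[, k] <- stats::rbeta(P, a, b)
  }

  G <- matrix(0L, nrow = n, ncol = P, dimnames = list(ids, snp_ids))
  for (k in seq_len(config$n_subpops)) {
    idx <- which(subpop == k)
    if (!length(idx)) next
    G[idx, ] <- matrix(stats::rbinom(length(idx) * P, size = 2,
                                     prob = rep(freqs[, k],
                                                each = length(idx))),
                       nrow = length(idx))
  }
  # re-orient to pooled minor allele
  flip <- colMeans(G) / 2 > 0.5
  if (any(flip)) G[, flip] <- 2L - G[, flip]

  gene_map <- data.frame(gene_id = gene_of[!is.na(gene_of)],
                         snp_id = snp_ids[!is.na(gene_of)],
                         stringsAsFactors = FALSE)
  list(G_wide = G, gene_map = gene_map, subpop = subpop)
}

simulate_covariates <- function(config) {
  n <- config$n_samples
  data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    Sex = stats::rbinom(n, 1, 0.5),
    Age = stats::rnorm(n, 49, 12),
    Smoking = stats::rbinom(n, 1, config$smoking_prevalence),
    stringsAsFactors = FALSE)
}

#' Simulate replicated quantitative phenotypes on fixed genotypes
#'
#' For replicate r:
#' `y = beta_sex Sex + beta_age Age_z + beta_smoking s +
#'  sum_genes beta_main c_gene + beta_gxe s * c_gxe + shift(subpop) + e`,
#' `e ~ N(0, sigma_e^2)`, independently across replicates. `c_gene` is the
#' collapsed (burden) genotype, so the interaction acts on the genotype sum
#' and the burden-based models M12/M14 are the well-specified ones.
#'
#' @param G_wide,gene_map,subpop Output of [simulate_genotypes()].
#' @param covariates Covariate table (`Sex`, `Age`, `Smoking`).
#' @param config A [sim_config()].
#' @param seed Seed for the phenotype noise; defaults to
#'   `config$seed + 1000` so phenotypes can be redrawn (e.g. on an effect
#'   grid) while genotypes stay fixed.
#' @return n x n_replicates matrix `Y`.
#' @export
simulate_phenotypes <- function(G_wide, gene_map, covariates, subpop,
                                config, seed = config$seed + 1000L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- nrow(G_wide)
  age <- covariates$Age
  age_z <- (age - mean(age)) / stats::sd(age)
  s <- covariates$Smoking
  base <- config$beta_sex * covariates$Sex + config$beta_age * age_z +
    config$beta_smoking * s
  for (g in config$genes) {
    if (g$beta_main == 0 && g$beta_gxe == 0) next
    snps <- gene_map$snp_id[gene_map$gene_id == g$gene_id]
    if (!length(snps))
      stop("gene `", g$gene_id, "` in effects list but not in gene map",
           call. = FALSE)
    cg <- rowSums(G_wide[, snps, drop = FALSE])
    base <- base + g$beta_main * cg + g$beta_gxe * s * cg
  }
  shift <- config$subpop_trait_shift * (subpop - mean(subpop))
  mu <- base + shift
  R <- config$n_replicates
  Y <- mu + matrix(stats::rnorm(n * R, 0, config$sigma_e), n, R)
  dimnames(Y) <- list(rownames(G_wide), sprintf("rep_%03d", seq_len(R)))
  Y
}

truth_labels <- function(config) {
  vapply(config$genes, function(g) {
    if (g$beta_gxe != 0) "gxe"
    else if (g$beta_main != 0) "main_only"
    else "null"
  }, character(1), USE.NAMES = FALSE) |>
    stats::setNames(vapply(config$genes, `[[`, "", "gene_id"))
}

#' Generate the full replicate set
#'
#' Draws genotypes, covariates and all phenotype replicates for a
#' configuration; deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return An object of class `replicate_set`: `G_wide`, `gene_map`,
#'   `covariates`, `Y`, `truth` (per-gene labels `null` / `main_only` /
#'   `gxe`), `subpop`, `config`.
#' @export
simulate_replicates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  geno <- simulate_genotypes(config)
  set.seed(config$seed + 500L)
  covariates <- simulate_covariates(config)
  Y <- simulate_phenotypes(geno$G_wide, geno$gene_map, covariates,
                           geno$subpop, config)
  structure(list(G_wide = geno$G_wide, gene_map = geno$gene_map,
                 covariates = covariates, Y = Y,
                 truth = truth_labels(config), subpop = geno$subpop,
                 config = config),
            class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  cat("<replicate_set> ", nrow(x$G_wide), " samples, ",
      ncol(x$G_wide), " SNPs (", length(unique(x$gene_map$gene_id)),
      " genes), ", ncol(x$Y), " phenotype replicates\n", sep = "")
  invisible(x)
}

#' Write / read a replicate set as plain-text fixture files
#'
#' Writes `genotypes.tsv` (sample_id + one column per SNP),
#' `genemap.tsv` (`gene_id`, `snp_id`), `covariates.tsv`,
#' `phenotypes.tsv` (sample_id + one column per replicate) and
#' `sidecar.json` (configuration, truth labels, subpopulation labels).
#'
#' @param rs A `replicate_set`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(rs, dir) {
  stopifnot(inherits(rs, "replicate_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genotypes(rs$G_wide, file.path(dir, "genotypes.tsv"))
  utils::write.table(rs$gene_map, file.path(dir, "genemap.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(rs$covariates, file.path(dir, "covariates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_phenotypes(rs$Y, file.path(dir, "phenotypes.tsv"))
  sidecar <- list(config = unclass(rs$config),
                  truth = as.list(rs$truth),
                  subpop = rs$subpop)
  jsonlite::write_json(sidecar, file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(dir) {
  G <- read_genotypes(file.path(dir, "genotypes.tsv"))
  gene_map <- utils::read.delim(file.path(dir, "genemap.tsv"),
                                stringsAsFactors = FALSE)
  covariates <- utils::read.delim(file.path(dir, "covariates.tsv"),
                                  stringsAsFactors = FALSE)
  Y <- read_phenotypes(file.path(dir, "phenotypes.tsv"))
  sidecar <- jsonlite::read_json(file.path(dir, "sidecar.json"),
                                 simplifyVector = TRUE)
  cfg_list <- sidecar$config
  cfg_list$genes <- lapply(seq_len(nrow(cfg_list$genes)), function(i) {
    g <- cfg_list$genes[i, ]
    sim_gene(g$gene_id, g$n_snps, g$rare_fraction,
             unlist(g$rare_maf_range), unlist(g$common_maf_range),
             g$beta_main, g$beta_gxe)
  })
  config <- do.call(sim_config, cfg_list)
  structure(list(G_wide = G, gene_map = gene_map, covariates = covariates,
                 Y = Y, truth = unlist(sidecar$truth),
                 subpop = as.integer(sidecar$subpop), config = config),
            class = "replicate_set")
}

# --- tabular I/O (design-module external interfaces) ----------------------

#' Read / write genotype, covariate and phenotype tables
#'
#' Genotype TSV: rows = samples, first column `sample_id`, remaining
#' columns SNP minor-allele counts in \{0, 1, 2\}. Phenotype TSV: first
#' column `sample_id`, remaining columns one phenotype replicate each.
#'
#' @param path File path.
#' @name tabular_io
#' @export
read_genotypes <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  G <- as.matrix(df[, -1L, drop = FALSE])
  rownames(G) <- as.character(df[[1L]])
  storage.mode(G) <- "integer"
  G
}

#' @rdname tabular_io
#' @param G Genotype matrix with sample IDs as rownames.
#' @export
write_genotypes <- function(G, path) {
  df <- data.frame(sample_id = rownames(G), G, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname tabular_io
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  Y <- as.matrix(df[, -1L, drop = FALSE])
  rownames(Y) <- as.character(df[[1L]])
  Y
}

#' @rdname tabular_io
#' @param Y Phenotype matrix with sample IDs as rownames.
#' @export
write_phenotypes <- function(Y, path) {
  df <- data.frame(sample_id = rownames(Y), Y, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname tabular_io
#' @details `read_vcf_genotypes()` converts a VCF (GT field) to minor-allele
#'   counts: per site the ALT dosage is counted, then re-oriented so the
#'   recorded allele is the minor allele in the sample, with exact 50/50
#'   ties broken toward ALT. Requires the `VariantAnnotation` package.
#' @export
read_vcf_genotypes <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("reading VCF requires the VariantAnnotation package",
         call. = FALSE)
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT   # sites x samples
  alt_dosage <- function(x) {
    alleles <- strsplit(x, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_integer_)
    sum(alleles != "0")
  }
  counts <- apply(gt, c(1L, 2L), alt_dosage)
  G <- t(counts)                           # samples x sites
  freq <- colMeans(G, na.rm = TRUE) / 2
  flip <- !is.na(freq) & freq > 0.5        # ties stay on ALT
  G[, flip] <- 2L - G[, flip]
  G
}
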
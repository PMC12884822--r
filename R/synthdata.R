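#' Simulation configuration
#'
#' Bundles the parameters of the synthetic-data generators. Defaults describe a
#' small but realistic study: a handful of cell types with negative-binomial
#' single-cell counts and planted marker genes, Dirichlet cell fractions mixed
#' into noisy bulk profiles, Hardy-Weinberg genotypes, expression generated
#' under the genotype x cell-fraction interaction model, binomial
#' haplotype-specific ASE counts, and paired GWAS/eQTL summary statistics.
#'
#' @param n_cell_types Number of cell types.
#' @param n_genes Number of genes.
#' @param cells_per_type Cells simulated per cell type.
#' @param n_bulk_samples Number of bulk mixtures.
#' @param n_snps Number of SNPs.
#' @param maf_range Length-2 numeric in (0, 0.5]: minor allele frequencies are
#'   drawn uniformly from this interval.
#' @param dirichlet_alpha Dirichlet concentration vector of length
#'   `n_cell_types` for the bulk mixing fractions.
#' @param bulk_noise_sd Log-scale standard deviation of the multiplicative
#'   lognormal noise applied to bulk mixtures.
#' @param effect_sizes Named numeric with elements `beta_g`, `beta_b`,
#'   `beta_gxb`: the genotype, cell-fraction and interaction effects.
#' @param markers_per_type Marker genes planted per cell type.
#' @param marker_fold Fold elevation of a marker's mean in its own type.
#' @param dispersion Negative-binomial dispersion (variance = mu + dispersion *
#'   mu^2) of the single-cell counts.
#' @param ase_depth Total read depth per ASE site.
#' @param gwas_n GWAS sample size for summary-statistic simulation.
#' @param seed Integer seed; identical seeds give bit-identical output.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_cell_types = 4L, n_genes = 400L, cells_per_type = 60L,
                       n_bulk_samples = 200L, n_snps = 100L,
                       maf_range = c(0.05, 0.5),
                       dirichlet_alpha = rep(1, n_cell_types),
                       bulk_noise_sd = 0.2,
                       effect_sizes = c(beta_g = 0.2, beta_b = 0.5, beta_gxb = 0.5),
                       markers_per_type = 10L, marker_fold = 8,
                       dispersion = 0.5,
                       ase_depth = 100L, gwas_n = 10000L, seed = 1L) {
  cfg <- list(
    n_cell_types = check_count(n_cell_types, "n_cell_types"),
    n_genes = check_count(n_genes, "n_genes"),
    cells_per_type = check_count(cells_per_type, "cells_per_type"),
    n_bulk_samples = check_count(n_bulk_samples, "n_bulk_samples"),
    n_snps = check_count(n_snps, "n_snps", min = 0L),
    maf_range = maf_range,
    dirichlet_alpha = dirichlet_alpha,
    bulk_noise_sd = bulk_noise_sd,
    effect_sizes = effect_sizes,
    markers_per_type = check_count(markers_per_type, "markers_per_type"),
    marker_fold = marker_fold,
    dispersion = dispersion,
    ase_depth = check_count(ase_depth, "ase_depth"),
    gwas_n = check_count(gwas_n, "gwas_n"),
    seed = check_seed(seed)
  )
  if (length(cfg$maf_range) != 2L || any(cfg$maf_range <= 0) ||
      any(cfg$maf_range > 0.5) || cfg$maf_range[1] > cfg$maf_range[2]) {
    stop_cellqtl("`maf_range` must lie within (0, 0.5] with min <= max")
  }
  if (length(cfg$dirichlet_alpha) != cfg$n_cell_types || any(cfg$dirichlet_alpha <= 0)) {
    stop_cellqtl("`dirichlet_alpha` must be positive and of length n_cell_types")
  }
  if (cfg$bulk_noise_sd < 0) stop_cellqtl("`bulk_noise_sd` must be >= 0")
  if (!all(c("beta_g", "beta_b", "beta_gxb") %in% names(cfg$effect_sizes))) {
    stop_cellqtl("`effect_sizes` needs named elements beta_g, beta_b, beta_gxb")
  }
  if (cfg$n_genes < cfg$n_cell_types * cfg$markers_per_type) {
    stop_cellqtl("n_genes must be >= n_cell_types * markers_per_type")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a labelled single-cell count reference
#'
#' Draws negative-binomial counts for `n_cell_types` cell types with
#' `markers_per_type` marker genes per type whose mean is elevated
#' `marker_fold`-fold in their own type. Per-gene baseline means are lognormal
#' so the depth profile is skewed, as in real single-cell data.
#'
#' @param cfg A [sim_config()].
#' @return A list with `counts` (cells x genes integer matrix), `cells`
#'   (data.frame of `cell_id`, `cell_type`), and `marker_sets` (named list of
#'   planted marker gene ids per cell type).
#' @export
simulate_single_cell_reference <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_rng(cfg$seed, {
    K <- cfg$n_cell_types; G <- cfg$n_genes; C <- cfg$cells_per_type
    genes <- sprintf("gene%04d", seq_len(G))
    types <- sprintf("type%02d", seq_len(K))
    base_mu <- exp(rnorm(G, mean = 0.5, sd = 1))          # skewed baseline means
    marker_sets <- vector("list", K); names(marker_sets) <- types
    mu <- matrix(rep(base_mu, each = K), nrow = K)        # type x gene means
    for (k in seq_len(K)) {
      idx <- ((k - 1L) * cfg$markers_per_type + 1L):(k * cfg$markers_per_type)
      mu[k, idx] <- mu[k, idx] * cfg$marker_fold
      marker_sets[[k]] <- genes[idx]
    }
    labels <- rep(types, each = C)
    counts <- matrix(0L, nrow = K * C, ncol = G,
                     dimnames = list(sprintf("cell%05d", seq_len(K * C)), genes))
    size <- 1 / cfg$dispersion
    for (k in seq_len(K)) {
      rows <- which(labels == types[k])
      counts[rows, ] <- matrix(
        rnbinom(length(rows) * G, mu = rep(mu[k, ], each = length(rows)), size = size),
        nrow = length(rows))
    }
    list(counts = counts,
         cells = data.frame(cell_id = rownames(counts), cell_type = labels,
                            stringsAsFactors = FALSE),
         marker_sets = marker_sets)
  })
}

#' Draw rows from a Dirichlet distribution
#'
#' @param n Number of draws.
#' @param alpha Concentration vector.
#' @return An `n` x `length(alpha)` matrix whose rows sum to 1.
#' @export
rdirichlet <- function(n, alpha) {
  x <- matrix(rgamma(n * length(alpha), shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}

#' Simulate bulk mixtures from a signature matrix
#'
#' Each bulk column is the signature-weighted mixture `S %*% w` multiplied by
#' i.i.d. per-gene lognormal noise `exp(N(0, noise_sd^2))`. Mixing fractions
#' are drawn from a Dirichlet unless supplied.
#'
#' @param signature Genes x cell types nonnegative matrix (or `signature_matrix`).
#' @param n_samples Number of bulk samples.
#' @param dirichlet_alpha Concentration vector, one per cell type.
#' @param noise_sd Log-scale noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @param fractions Optional fixed samples x cell types fraction matrix; rows
#'   must sum to 1. Overrides the Dirichlet draw.
#' @return List with `bulk` (genes x samples matrix) and `fractions`
#'   (samples x cell types matrix).
#' @export
simulate_bulk_mixtures <- function(signature, n_samples, dirichlet_alpha,
                                   noise_sd = 0.2, seed = 1L, fractions = NULL) {
  S <- as.matrix(signature)
  if (ncol(S) < 2L) stop_cellqtl("signature needs >= 2 cell types")
  if (noise_sd < 0) stop_cellqtl("noise_sd must be >= 0")
  with_rng(seed, {
    if (is.null(fractions)) {
      if (length(dirichlet_alpha) != ncol(S)) {
        stop_cellqtl("dirichlet_alpha length must equal the number of cell types")
      }
      W <- rdirichlet(n_samples, dirichlet_alpha)
    } else {
      W <- as.matrix(fractions)
      if (ncol(W) != ncol(S) || nrow(W) != n_samples) {
        stop_cellqtl("fractions must be n_samples x n_cell_types")
      }
    }
    colnames(W) <- colnames(S)
    bulk <- S %*% t(W)
    if (noise_sd > 0) {
      bulk <- bulk * exp(matrix(rnorm(length(bulk), 0, noise_sd), nrow = nrow(bulk)))
    }
    rownames(bulk) <- rownames(S)
    colnames(bulk) <- sprintf("sample%04d", seq_len(n_samples))
    rownames(W) <- colnames(bulk)
    list(bulk = bulk, fractions = W)
  })
}

#' Simulate Hardy-Weinberg genotype dosages
#'
#' Dosages are Binomial(2, f) with allele frequency f drawn uniformly from
#' `maf_range` per SNP. SNPs sit on one synthetic chromosome at fixed spacing,
#' 1-based positions. An optional block-copy mode duplicates columns to create
#' perfect-LD blocks.
#'
#' @param n_samples Number of individuals.
#' @param n_snps Number of SNPs (0 gives an empty matrix with valid metadata).
#' @param maf_range Length-2 numeric in (0, 0.5].
#' @param seed Integer seed.
#' @param spacing Base-pair distance between adjacent SNPs (default 1000).
#' @param chrom Chromosome label.
#' @param ld_block_size If > 1, each drawn SNP is copied this many times so the
#'   matrix consists of perfect-LD blocks (total columns still `n_snps`).
#' @return A `genotype_matrix`: list with `dosages` (samples x SNPs matrix of
#'   0/1/2) and `snps` (data.frame id, chrom, pos).
#' @export
simulate_genotypes <- function(n_samples, n_snps, maf_range = c(0.05, 0.5),
                               seed = 1L, spacing = 1000L, chrom = "1",
                               ld_block_size = 1L) {
  n_samples <- check_count(n_samples, "n_samples")
  n_snps <- check_count(n_snps, "n_snps", min = 0L)
  if (any(maf_range <= 0) || any(maf_range > 0.5)) {
    stop_cellqtl("maf_range must lie within (0, 0.5]")
  }
  with_rng(seed, {
    n_draw <- if (ld_block_size > 1L) ceiling(n_snps / ld_block_size) else n_snps
    f <- runif(n_draw, maf_range[1], maf_range[2])
    g <- matrix(rbinom(n_samples * n_draw, 2L, rep(f, each = n_samples)),
                nrow = n_samples)
    if (ld_block_size > 1L && n_snps > 0L) {
      g <- g[, rep(seq_len(n_draw), each = ld_block_size)[seq_len(n_snps)], drop = FALSE]
    }
    snp_ids <- if (n_snps > 0L) sprintf("snp%05d", seq_len(n_snps)) else character(0)
    dimnames(g) <- list(sprintf("ind%04d", seq_len(n_samples)), snp_ids)
    structure(list(
      dosages = g,
      snps = data.frame(id = snp_ids, chrom = rep(chrom, n_snps),
                        pos = if (n_snps > 0L) spacing * (seq_len(n_snps) - 1L) + 1L
                              else integer(0),
                        stringsAsFactors = FALSE)),
      class = "genotype_matrix")
  })
}

#' Simulate expression under the interaction model
#'
#' Generates `y = b0 + beta_g * g + beta_b * b + beta_gxb * g * b + A gamma + e`
#' with `e ~ N(0, noise_sd^2)` -- the same linear model the ieQTL stage fits.
#'
#' @param g Genotype dosage vector.
#' @param b Cell-fraction (enrichment) vector, same length as `g`.
#' @param effects Named numeric with `beta_g`, `beta_b`, `beta_gxb`.
#' @param noise_sd Residual standard deviation (>= 0).
#' @param intercept Intercept `b0` (default 0).
#' @param covariates Optional samples x covariates matrix `A`.
#' @param covariate_effects Coefficients for `A` (default all 1).
#' @param seed Integer seed.
#' @return Numeric phenotype vector.
#' @export
simulate_ieqtl_expression <- function(g, b, effects, noise_sd = 1, intercept = 0,
                                      covariates = NULL, covariate_effects = NULL,
                                      seed = 1L) {
  if (length(g) != length(b)) stop_cellqtl("g and b must have the same length")
  if (noise_sd < 0) stop_cellqtl("noise_sd must be >= 0")
  y <- intercept + effects[["beta_g"]] * g + effects[["beta_b"]] * b +
    effects[["beta_gxb"]] * g * b
  if (!is.null(covariates)) {
    A <- as.matrix(covariates)
    if (nrow(A) != length(g)) stop_cellqtl("covariates must have one row per sample")
    gamma <- covariate_effects %||% rep(1, ncol(A))
    y <- y + drop(A %*% gamma)
  }
  if (noise_sd > 0) y <- y + with_rng(seed, rnorm(length(g), 0, noise_sd))
  y
}

#' Simulate haplotype-specific ASE read counts
#'
#' For heterozygous individual i with cell-type enrichment `b_i`, the
#' alternative-haplotype read count is Binomial(depth, pi_i) with a
#' logit-linear link `log2(pi_i / (1 - pi_i)) = afc * b_i`, so the allelic
#' imbalance grows with the cell fraction and the allelic fold change is
#' recoverable by correlating per-individual aFC with enrichment.
#'
#' @param het_individuals Number of heterozygous individuals.
#' @param afc Planted allelic fold change (log2 scale) at full enrichment.
#' @param fractions Per-individual enrichment values `b_i`; recycled or drawn
#'   Uniform(0, 1) when `NULL`.
#' @param depth Total reads per individual (>= 1).
#' @param seed Integer seed.
#' @return data.frame with `individual`, `ref_hap_reads`, `alt_hap_reads`,
#'   `enrichment`, `is_het`.
#' @export
simulate_ase_counts <- function(het_individuals, afc, fractions = NULL,
                                depth = 100L, seed = 1L) {
  n <- check_count(het_individuals, "het_individuals")
  depth <- check_count(depth, "depth")
  with_rng(seed, {
    b <- fractions %||% runif(n)
    b <- rep_len(b, n)
    p_alt <- stats::plogis(log(2) * afc * b)
    alt <- rbinom(n, depth, p_alt)
    data.frame(individual = sprintf("ind%04d", seq_len(n)),
               ref_hap_reads = depth - alt, alt_hap_reads = alt,
               enrichment = b, is_het = TRUE, stringsAsFactors = FALSE)
  })
}

#' Simulate a paired GWAS/eQTL summary-statistic locus
#'
#' Z-scores are standard normal at non-causal SNPs (unlinked) and centred at
#' `effect * sqrt(n)` at the causal SNP of each trait. `shared` plants the same
#' causal SNP in both traits, `distinct` different SNPs, `null` leaves the GWAS
#' with no causal SNP (the eQTL keeps one). Betas and SEs are on a
#' standardized scale: `se = 1/sqrt(n)`, `beta = z * se`.
#'
#' @param scenario One of `"shared"`, `"distinct"`, `"null"`.
#' @param n_snps Number of SNPs at the locus (>= 2).
#' @param gwas_n,eqtl_n Per-trait sample sizes.
#' @param effect Standardized per-allele effect at the causal SNP.
#' @param seed Integer seed.
#' @param spacing Base-pair spacing of the SNPs.
#' @return List with `gwas` and `eqtl` summary data.frames (snp, chrom, pos,
#'   beta, se, p, n) and `truth` (scenario and causal indices).
#' @export
simulate_gwas_pair <- function(scenario, n_snps, gwas_n = 10000L, eqtl_n = 10000L,
                               effect = 0.1, seed = 1L, spacing = 1000L) {
  scenario <- match.arg(scenario, c("shared", "distinct", "null"))
  n_snps <- check_count(n_snps, "n_snps", min = 2L)
  with_rng(seed, {
    causal_eqtl <- sample.int(n_snps, 1L)
    causal_gwas <- switch(scenario,
      shared = causal_eqtl,
      distinct = sample(setdiff(seq_len(n_snps), causal_eqtl), 1L),
      null = NA_integer_)
    make_trait <- function(n, causal) {
      z <- rnorm(n_snps)
      if (!is.na(causal)) z[causal] <- z[causal] + effect * sqrt(n)
      se <- rep(1 / sqrt(n), n_snps)
      data.frame(snp = sprintf("snp%05d", seq_len(n_snps)), chrom = "1",
                 pos = spacing * (seq_len(n_snps) - 1L) + 1L,
                 beta = z * se, se = se, p = 2 * pnorm(-abs(z)), n = n,
                 stringsAsFactors = FALSE)
    }
    list(gwas = make_trait(gwas_n, causal_gwas),
         eqtl = make_trait(eqtl_n, causal_eqtl),
         truth = list(scenario = scenario, causal_gwas = causal_gwas,
                      causal_eqtl = causal_eqtl))
  })
}

#' Simulate GWAS chi-square statistics with planted heritability enrichment
#'
#' Per-SNP heritability is split so SNPs inside the annotation carry
#' `prop_h2_annot` of the total `h2`. Z-scores are drawn `N(0, 1 + N * h2_j)`
#' (the no-LD expectation of stratified LD-score regression), and chi-square is
#' their square.
#'
#' @param membership Logical/0-1 vector marking SNPs inside the annotation.
#' @param N GWAS sample size.
#' @param h2 Total SNP heritability.
#' @param prop_h2_annot Share of `h2` carried by annotation SNPs.
#' @param seed Integer seed.
#' @return List with `chi2` (vector) and `h2_per_snp` (vector).
#' @export
simulate_gwas_chi2 <- function(membership, N, h2 = 0.5, prop_h2_annot = 0.5,
                               seed = 1L) {
  m <- as.logical(membership)
  M_in <- sum(m); M_out <- sum(!m)
  if (M_in == 0L || M_out == 0L) stop_cellqtl("membership must split the SNPs")
  h2_per <- numeric(length(m))
  h2_per[m] <- h2 * prop_h2_annot / M_in
  h2_per[!m] <- h2 * (1 - prop_h2_annot) / M_out
  with_rng(seed, {
    z <- rnorm(length(m), 0, sqrt(1 + N * h2_per))
    list(chi2 = z^2, h2_per_snp = h2_per)
  })
}
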
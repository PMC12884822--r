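#' Rank-based inverse normal transform
#'
#' Maps values through `qnorm((rank - 0.5) / n)` with average ranks for ties.
#' The output is strictly monotone in the input over distinct values, so the
#' transform is invariant to any strictly monotone re-expression of the input.
#'
#' @param values Numeric vector with at least 2 distinct values.
#' @return Transformed vector of the same length.
#' @export
inverse_normal_transform <- function(values) {
  if (length(unique(values[!is.na(values)])) < 2L) {
    stop_cellqtl("inverse normal transform needs >= 2 distinct values")
  }
  qnorm((rank(values, ties.method = "average") - 0.5) / length(values))
}

#' TMM library-composition normalisation
#'
#' Computes trimmed-mean-of-M-values scaling factors (via edgeR's
#' implementation: reference sample with upper quartile closest to the mean
#' upper quartile, genes zero in either sample excluded, 30% two-sided trim on
#' M-values and 5% on A-values, precision-weighted mean M, factors rescaled to
#' geometric mean 1) and returns counts scaled to per-million on the
#' effective library sizes.
#'
#' @param counts Genes x samples nonnegative count matrix.
#' @return List with `factors` (per-sample TMM factors) and `normalized`
#'   (genes x samples matrix: `count / (library_size * factor) * 1e6`).
#' @export
tmm_normalize <- function(counts) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  if (any(lib <= 0)) stop_cellqtl("every sample must have a positive library size")
  f <- edgeR::calcNormFactors(edgeR::DGEList(counts = counts),
                              method = "TMM")$samples$norm.factors
  normalized <- sweep(counts, 2, lib * f, "/") * 1e6
  list(factors = f, normalized = normalized)
}

#' Interaction MAF filter on enrichment-sorted halves
#'
#' Samples are sorted by the cell-type enrichment `b`; the SNP is kept iff its
#' allele frequency `f` satisfies `maf_min <= f <= 1 - maf_min` in BOTH the
#' top 50% and the bottom 50% of samples. With odd n the middle sample goes to
#' the bottom half.
#'
#' @param g Dosage vector (0/1/2; missing allowed, ignored per half).
#' @param b Enrichment vector, no missing values.
#' @param maf_min Minor-allele-frequency floor (default 0.05).
#' @return `TRUE` (keep) or `FALSE` (drop).
#' @export
interaction_maf_filter <- function(g, b, maf_min = 0.05) {
  n <- length(g)
  if (n != length(b)) stop_cellqtl("g and b must have the same length")
  if (anyNA(b)) stop_cellqtl("b must not contain missing values")
  if (n < 4L) stop_cellqtl("need at least 4 samples")
  ord <- order(b)                       # ascending; bottom half first
  n_bottom <- ceiling(n / 2)            # odd n: middle sample -> bottom half
  halves <- list(bottom = g[ord[seq_len(n_bottom)]],
                 top = g[ord[(n_bottom + 1L):n]])
  ok <- vapply(halves, function(h) {
    h <- h[!is.na(h)]
    if (length(h) == 0L) return(FALSE)
    f <- mean(h) / 2
    f >= maf_min && f <= 1 - maf_min
  }, logical(1))
  all(ok)
}

#' Fit the genotype x cell-fraction interaction model
#'
#' Ordinary least squares for `y ~ g + b + g:b + A` with an intercept. The
#' reported test is the two-sided t-test on the interaction coefficient with
#' `n - rank` degrees of freedom.
#'
#' @param y Phenotype vector (conventionally inverse-normal transformed TMM
#'   expression).
#' @param g Genotype dosage vector.
#' @param b Cell-type enrichment vector.
#' @param A Optional samples x covariates matrix.
#' @return List with `beta` (named: intercept, g, b, gxb, covariates), `se`,
#'   `t_gxb`, `p_nominal`, `df`; or `NULL` (with a warning) when the design is
#'   rank deficient.
#' @export
fit_interaction_model <- function(y, g, b, A = NULL) {
  n <- length(y)
  if (length(g) != n || length(b) != n) stop_cellqtl("y, g, b lengths differ")
  X <- cbind(intercept = 1, g = g, b = b, gxb = g * b)
  if (!is.null(A)) {
    A <- as.matrix(A)
    colnames(A) <- colnames(A) %||% sprintf("cov%d", seq_len(ncol(A)))
    X <- cbind(X, A)
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    warning("rank-deficient design: record skipped")
    return(NULL)
  }
  beta <- qr.coef(qr_x, y)
  res <- y - drop(X %*% beta)
  df <- n - qr_x$rank
  if (df <= 0) {
    warning("no residual degrees of freedom")
    return(NULL)
  }
  sigma2 <- sum(res^2) / df
  xtx_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(pmax(diag(xtx_inv) * sigma2, 0))
  names(se) <- colnames(X)
  t_gxb <- beta[["gxb"]] / se[["gxb"]]
  list(beta = beta, se = se, t_gxb = t_gxb,
       p_nominal = 2 * pt(-abs(t_gxb), df), df = df)
}

#' Nominal cis scan of the interaction model around one gene
#'
#' Tests every SNP on the gene's chromosome with `|pos - tss| <= window`
#' (closed at the boundary; the stored TSS is used as-is for both strands).
#' Missing dosages are mean-imputed per SNP; SNPs failing the interaction MAF
#' filter are dropped.
#'
#' @param gene List/row with `gene_id`, `chrom`, `tss`.
#' @param genotypes A `genotype_matrix` (see [simulate_genotypes()]).
#' @param y Phenotype vector aligned to the genotype samples.
#' @param b Enrichment vector aligned likewise.
#' @param A Optional covariate matrix.
#' @param window Cis-window half-width in bp (default 1e6).
#' @param maf_min Interaction MAF threshold (default 0.05).
#' @return data.frame of nominal ieQTL records (`gene_id`, `snp_id`, `beta_g`,
#'   `beta_b`, `beta_gxb`, `se_gxb`, `t_gxb`, `p_nominal`); zero rows when no
#'   SNP survives.
#' @export
cis_scan <- function(gene, genotypes, y, b, A = NULL, window = 1e6,
                     maf_min = 0.05) {
  snps <- genotypes$snps
  in_win <- snps$chrom == gene$chrom & abs(snps$pos - gene$tss) <= window
  empty <- data.frame(gene_id = character(0), snp_id = character(0),
                      beta_g = numeric(0), beta_b = numeric(0),
                      beta_gxb = numeric(0), se_gxb = numeric(0),
                      t_gxb = numeric(0), p_nominal = numeric(0))
  if (!any(in_win)) return(empty)
  rows <- lapply(which(in_win), function(j) {
    g <- genotypes$dosages[, j]
    if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
    if (!interaction_maf_filter(g, b, maf_min)) return(NULL)
    fit <- fit_interaction_model(y, g, b, A)
    if (is.null(fit)) return(NULL)
    data.frame(gene_id = gene$gene_id, snp_id = snps$id[j],
               beta_g = fit$beta[["g"]], beta_b = fit$beta[["b"]],
               beta_gxb = fit$beta[["gxb"]], se_gxb = fit$se[["gxb"]],
               t_gxb = fit$t_gxb, p_nominal = fit$p_nominal,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}

#' Effective number of tests (eigenMT) and gene-level p-value
#'
#' Estimates the effective number of independent tests in a cis window from
#' the eigenvalues of the SNP-SNP Pearson correlation matrix, computed in
#' non-overlapping windows of `window_size` SNPs: per window, `M_eff` is the
#' smallest k whose top-k eigenvalues explain at least `var_threshold` of the
#' total variance, and window contributions are summed. The gene-level p-value
#' is `min(1, p_nominal_min * M_eff)`.
#'
#' @param window_genotypes Samples x SNPs dosage matrix of the gene's cis
#'   window (constant columns are ignored; all-constant gives `M_eff = 1`).
#' @param p_nominal_min The gene's minimum nominal p-value.
#' @param var_threshold Variance-explained threshold (default 0.99).
#' @param window_size SNPs per eigen-decomposition window (default 200).
#' @return List with `m_eff` and `p_eigenmt`.
#' @export
eigenmt_correct <- function(window_genotypes, p_nominal_min,
                            var_threshold = 0.99, window_size = 200L) {
  G <- as.matrix(window_genotypes)
  if (ncol(G) < 1L) stop_cellqtl("need at least one SNP")
  keep <- apply(G, 2, function(x) sd(x, na.rm = TRUE) > 0)
  G <- G[, keep, drop = FALSE]
  if (ncol(G) == 0L) {
    m_eff <- 1L
  } else {
    starts <- seq(1L, ncol(G), by = window_size)
    m_eff <- sum(vapply(starts, function(s) {
      block <- G[, s:min(s + window_size - 1L, ncol(G)), drop = FALSE]
      ev <- eigen(cor(block), symmetric = TRUE, only.values = TRUE)$values
      ev <- pmax(ev, 0)
      which(cumsum(ev) >= var_threshold * sum(ev))[1]
    }, numeric(1)))
  }
  list(m_eff = m_eff, p_eigenmt = min(1, p_nominal_min * m_eff))
}

#' Call ieGenes with Benjamini-Hochberg FDR on eigenMT-corrected p-values
#'
#' Takes one record per gene (its top SNP with the eigenMT-corrected p-value),
#' applies BH across genes within each group (e.g. tissue x cell type), and
#' flags ieGenes at `fdr < fdr_max`.
#'
#' @param records data.frame with at least `gene_id` and `p_eigenmt`; optional
#'   `group` column for within-group adjustment.
#' @param fdr_max Significance threshold (default 0.05, strict).
#' @return The input with `fdr` and logical `ie_gene` columns added.
#' @export
call_iegenes <- function(records, fdr_max = 0.05) {
  stopifnot(all(c("gene_id", "p_eigenmt") %in% names(records)))
  grp <- if ("group" %in% names(records)) records$group else rep("all", nrow(records))
  records$fdr <- NA_real_
  for (g in unique(grp)) {
    idx <- grp == g
    records$fdr[idx] <- p.adjust(records$p_eigenmt[idx], method = "BH")
  }
  records$ie_gene <- records$fdr < fdr_max
  records
}

#' Map interaction eQTL for a set of genes
#'
#' Runs the full per-gene procedure: nominal cis scan, top-SNP selection,
#' eigenMT correction on the window genotypes, then BH across genes.
#'
#' @param genes data.frame of gene models (`gene_id`, `chrom`, `tss`).
#' @param genotypes A `genotype_matrix`.
#' @param expression Genes x samples phenotype matrix (rows named by
#'   `gene_id`); each row is inverse-normal transformed before fitting unless
#'   `transform = FALSE`.
#' @param b Enrichment vector (inverse-normal transformed internally unless
#'   `transform = FALSE`, mirroring common ieQTL practice).
#' @param A Optional covariates.
#' @param window,maf_min,fdr_max See [cis_scan()] and [call_iegenes()].
#' @param transform Apply [inverse_normal_transform()] to phenotype rows and
#'   `b` (default TRUE).
#' @return List with `top` (per-gene top-SNP records with `m_eff`,
#'   `p_eigenmt`, `fdr`, `ie_gene`) and `nominal` (all nominal records).
#' @export
map_ieqtl <- function(genes, genotypes, expression, b, A = NULL, window = 1e6,
                      maf_min = 0.05, fdr_max = 0.05, transform = TRUE) {
  expression <- as.matrix(expression)
  b_fit <- if (transform) inverse_normal_transform(b) else b
  nominal <- list(); top <- list()
  for (i in seq_len(nrow(genes))) {
    gene <- genes[i, ]
    if (!gene$gene_id %in% rownames(expression)) next
    y <- expression[gene$gene_id, ]
    if (length(unique(y)) < 2L) next    # constant expression: untestable
    y_fit <- if (transform) inverse_normal_transform(y) else y
    rec <- cis_scan(gene, genotypes, y_fit, b_fit, A, window, maf_min)
    if (nrow(rec) == 0L) next
    nominal[[gene$gene_id]] <- rec
    best <- rec[which.min(rec$p_nominal), , drop = FALSE]
    in_win <- genotypes$snps$chrom == gene$chrom &
      abs(genotypes$snps$pos - gene$tss) <= window
    em <- eigenmt_correct(genotypes$dosages[, in_win, drop = FALSE],
                          best$p_nominal)
    best$m_eff <- em$m_eff
    best$p_eigenmt <- em$p_eigenmt
    top[[gene$gene_id]] <- best
  }
  if (length(top) == 0L) {
    return(list(top = data.frame(), nominal = data.frame()))
  }
  top <- do.call(rbind, top)
  rownames(top) <- NULL
  top <- call_iegenes(top, fdr_max)
  list(top = top, nominal = do.call(rbind, c(nominal, list(make.row.names = FALSE))))
}
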
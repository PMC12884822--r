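#' Build a cell-type variant annotation from ranked markers
#'
#' Takes the `top_n` cell-type-specific genes by ascending p-value (ties:
#' larger |log2FC|, then gene id), anchors a symmetric interval
#' `[tss - flank, tss + flank]` (clipped at 1) on each gene's TSS, and records
#' the regions. Genes without coordinates are skipped with a warning.
#'
#' @param markers A `marker_table` restricted to one cell type (or with a
#'   `cell_type` column and `cell_type` argument given).
#' @param genes Gene-model data.frame with `gene_id`, `chrom`, `tss`.
#' @param cell_type Optional label selecting one cell type from `markers`.
#' @param top_n Genes kept (default 200).
#' @param flank Half-width of each region in bp (default 10000).
#' @return An `annotation_set`: list with `name`, `regions` (data.frame chrom,
#'   start, end, gene_id; 1-based closed intervals) and `genes` used.
#' @export
build_celltype_annotation <- function(markers, genes, cell_type = NULL,
                                      top_n = 200, flank = 10000) {
  m <- markers
  if (!is.null(cell_type)) m <- m[m$cell_type == cell_type, , drop = FALSE]
  if (nrow(m) == 0L) stop_cellqtl("no markers for the requested cell type")
  m <- m[order(m$p_value, -abs(m$log2_fold_change), m$gene), , drop = FALSE]
  sel <- head(m$gene, top_n)
  hit <- match(sel, genes$gene_id)
  if (anyNA(hit)) {
    warning(sprintf("%d selected genes lack coordinates and were skipped",
                    sum(is.na(hit))))
    sel <- sel[!is.na(hit)]
    hit <- hit[!is.na(hit)]
  }
  regions <- data.frame(chrom = genes$chrom[hit],
                        start = pmax(1, genes$tss[hit] - flank),
                        end = genes$tss[hit] + flank,
                        gene_id = sel, stringsAsFactors = FALSE)
  structure(list(name = cell_type %||% "annotation", regions = regions,
                 genes = sel),
            class = "annotation_set")
}

#' SNP membership in an annotation
#'
#' @param annotation An `annotation_set`.
#' @param snps data.frame with `chrom` and `pos` (1-based).
#' @return Logical vector: SNP lies inside at least one region (closed
#'   intervals).
#' @export
annotate_snps <- function(annotation, snps) {
  member <- rep(FALSE, nrow(snps))
  for (chr in unique(annotation$regions$chrom)) {
    reg <- annotation$regions[annotation$regions$chrom == chr, , drop = FALSE]
    idx <- which(snps$chrom == chr)
    if (length(idx) == 0L) next
    for (r in seq_len(nrow(reg))) {
      member[idx] <- member[idx] |
        (snps$pos[idx] >= reg$start[r] & snps$pos[idx] <= reg$end[r])
    }
  }
  member
}

#' Fisher-exact enrichment of significant GWAS variants in an annotation
#'
#' Builds the 2x2 table \{significant, not\} x \{in annotation, not\} over all
#' tested SNPs (the background), computes the two-sided Fisher's exact
#' p-value, and reports the cross-product odds ratio `ad/bc` (Haldane 0.5
#' correction applied only when some cell is zero, with `haldane = TRUE` in
#' the output). Zero significant SNPs give `p = 1` and an undefined OR.
#'
#' @param gwas Summary data.frame with `p` and (for membership) `chrom`, `pos`.
#' @param annotation An `annotation_set`, or a logical membership vector.
#' @param sig_threshold Genome-wide significance cutoff (default 5e-8, strict).
#' @return One-row data.frame: `odds_ratio`, `p_value`, counts `a` (sig & in),
#'   `b` (sig & out), `c` (nonsig & in), `d` (nonsig & out), `haldane` flag.
#' @export
fisher_enrichment <- function(gwas, annotation, sig_threshold = 5e-8) {
  member <- if (is.logical(annotation)) annotation else annotate_snps(annotation, gwas)
  sig <- gwas$p < sig_threshold
  a <- sum(sig & member); b <- sum(sig & !member)
  c_ <- sum(!sig & member); d <- sum(!sig & !member)
  if (a + b == 0L) {
    return(data.frame(odds_ratio = NA_real_, p_value = 1, a = a, b = b,
                      c = c_, d = d, haldane = FALSE))
  }
  p <- fisher.test(matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE),
                   alternative = "two.sided")$p.value
  haldane <- any(c(a, b, c_, d) == 0L)
  tab <- c(a, b, c_, d) + if (haldane) 0.5 else 0
  or <- (tab[1] * tab[4]) / (tab[2] * tab[3])
  data.frame(odds_ratio = or, p_value = p, a = a, b = b, c = c_, d = d,
             haldane = haldane)
}

#' BH adjustment across annotation-trait enrichment results
#'
#' @param results data.frame of stacked [fisher_enrichment()] rows.
#' @param fdr_max Significance threshold (default 0.05).
#' @return Input with `fdr` and `significant` columns added.
#' @export
adjust_enrichment <- function(results, fdr_max = 0.05) {
  results$fdr <- p.adjust(results$p_value, method = "BH")
  results$significant <- results$fdr < fdr_max
  results
}

#' Stratified heritability partitioning (no-LD LD-score regression)
#'
#' Fits `E[chi2_j] = N * sum_c tau_c * l(j, c) + intercept` by one-step
#' reweighted least squares (weights `1 / (2 * fitted^2)`, the chi-square
#' variance), with the intercept free. On unlinked SNPs the LD score of SNP j
#' in annotation c is its membership indicator, so per-SNP heritability is the
#' tau-weighted membership sum; per-annotation heritability, SNP shares and
#' the enrichment ratio `(h2_c / h2_total) / (M_c / M)` follow directly.
#' Standard errors (for tau and enrichment) come from a delete-one block
#' jackknife over `n_blocks` contiguous SNP blocks.
#'
#' @param chi2 Per-SNP GWAS chi-square statistics.
#' @param N GWAS sample size.
#' @param annotations SNPs x annotations 0/1 (or numeric LD score) matrix.
#'   Must include a base column covering every SNP.
#' @param ld_scores Optional SNPs x annotations LD-score matrix; defaults to
#'   `annotations` (the no-LD regime).
#' @param n_blocks Jackknife blocks (default 20).
#' @param min_snps Annotations with fewer member SNPs are dropped with a
#'   warning (default 10).
#' @return data.frame (`heritability_partition`): one row per annotation with
#'   `tau`, `prop_h2`, `prop_snps`, `enrichment`, `enrichment_se`,
#'   `coefficient_z`.
#' @export
sldsc_enrichment <- function(chi2, N, annotations, ld_scores = NULL,
                             n_blocks = 20L, min_snps = 10L) {
  annot <- as.matrix(annotations)
  if (is.null(colnames(annot))) colnames(annot) <- sprintf("annot%d", seq_len(ncol(annot)))
  if (!any(colSums(annot > 0) == nrow(annot))) {
    stop_cellqtl("a base annotation covering all SNPs is required")
  }
  small <- colSums(annot > 0) < min_snps
  if (any(small)) {
    warning(sprintf("dropping %d annotation(s) with < %d SNPs", sum(small), min_snps))
    annot <- annot[, !small, drop = FALSE]
  }
  L <- as.matrix(ld_scores %||% annot)
  M <- nrow(annot)
  blocks <- cut(seq_len(M), breaks = n_blocks, labels = FALSE)

  # In the no-LD regime the base annotation's LD-score column is constant 1
  # and therefore collinear with the free intercept. Constant columns are
  # absorbed into the intercept during the fit and their tau is recovered as
  # (intercept - 1) / (N * value): without confounding the expected intercept
  # is 1 plus the base polygenic term.
  const_col <- apply(L, 2, function(x) sd(x) == 0)
  if (sum(const_col) > 1L) {
    stop_cellqtl("at most one constant (base) LD-score column is identifiable")
  }
  # Overlapping annotations can make the design rank deficient (e.g. columns
  # that sum to the base). Per-SNP heritability is invariant to the resulting
  # gauge freedom, so non-estimable coefficients are fixed at 0.
  fit_tau <- function(keep) {
    X <- cbind(1, N * L[keep, !const_col, drop = FALSE])
    y <- chi2[keep]
    beta <- qr.coef(qr(X), y)
    beta[is.na(beta)] <- 0
    w <- 1 / (2 * pmax(drop(X %*% beta), 0.1)^2)
    beta <- qr.coef(qr(X * sqrt(w)), y * sqrt(w))
    beta[is.na(beta)] <- 0
    tau <- numeric(ncol(L))
    tau[!const_col] <- beta[-1]
    if (any(const_col)) tau[const_col] <- (beta[1] - 1) / (N * L[1, const_col])
    tau
  }
  summarize <- function(tau) {
    h2_snp <- drop(annot %*% tau)  # per-SNP h2 = tau-weighted membership
    h2_tot <- sum(h2_snp)
    h2_c <- drop(crossprod(annot > 0, h2_snp))
    prop_h2 <- h2_c / h2_tot
    prop_snps <- colSums(annot > 0) / M
    list(tau = tau, prop_h2 = prop_h2, enrich = prop_h2 / prop_snps,
         prop_snps = prop_snps)
  }

  full <- summarize(fit_tau(rep(TRUE, M)))
  jack <- lapply(seq_len(n_blocks), function(bl) {
    summarize(fit_tau(blocks != bl))
  })
  jt <- do.call(rbind, lapply(jack, `[[`, "tau"))
  je <- do.call(rbind, lapply(jack, `[[`, "enrich"))
  nb <- n_blocks
  tau_se <- sqrt((nb - 1) / nb * colSums(sweep(jt, 2, colMeans(jt))^2))
  enr_se <- sqrt((nb - 1) / nb * colSums(sweep(je, 2, colMeans(je))^2))
  res <- data.frame(annotation = colnames(annot), tau = full$tau,
                    prop_h2 = full$prop_h2, prop_snps = full$prop_snps,
                    enrichment = full$enrich, enrichment_se = enr_se,
                    coefficient_z = full$tau / tau_se,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("heritability_partition", "data.frame")
  res
}

#' Per-variant heritability enrichment of a two-set split
#'
#' For a partition of the SNPs into an in-annotation set and the rest,
#' returns `(h2_set / M_set) / (h2_total / M_total)` for the in-set: the
#' average per-variant heritability of annotation SNPs relative to the
#' genome-wide average.
#'
#' @param partition A `heritability_partition` from [sldsc_enrichment()] fitted
#'   with a base column plus one in-annotation column, or a list with
#'   `h2_set`, `m_set`, `h2_total`, `m_total`.
#' @param annotation Name of the in-annotation row (defaults to the first
#'   non-base annotation, i.e. the row with `prop_snps < 1`).
#' @return The per-variant enrichment ratio.
#' @export
per_variant_h2_enrichment <- function(partition, annotation = NULL) {
  if (is.list(partition) && !is.data.frame(partition) &&
      all(c("h2_set", "m_set", "h2_total", "m_total") %in% names(partition))) {
    if (partition$m_set == 0 || partition$m_total == 0) {
      stop_cellqtl("empty variant set")
    }
    return((partition$h2_set / partition$m_set) /
             (partition$h2_total / partition$m_total))
  }
  rows <- if (is.null(annotation)) which(partition$prop_snps < 1) else
    which(partition$annotation == annotation)
  if (length(rows) == 0L) stop_cellqtl("annotation row not found")
  row <- partition[rows[1], ]
  if (row$prop_snps == 0) stop_cellqtl("empty variant set")
  row$prop_h2 / row$prop_snps
}
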
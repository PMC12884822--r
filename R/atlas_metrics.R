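#' Quality-control filter for cells/nuclei
#'
#' Keeps a cell iff its gene count, UMI count and mitochondrial fraction all
#' lie inside the bounds. The exclusion rules are strict ("fewer than" /
#' "more than"), so boundary values pass.
#'
#' @param cells data.frame with columns `n_genes`, `n_umis`, `pct_mito`.
#' @param gene_bounds Inclusive (min, max) on detected genes.
#' @param umi_bounds Inclusive (min, max) on UMIs.
#' @param mito_max Maximum mitochondrial fraction (inclusive).
#' @return Logical keep mask, one element per row of `cells`.
#' @export
qc_filter <- function(cells, gene_bounds = c(200, 5000),
                      umi_bounds = c(500, 15000), mito_max = 0.05) {
  stopifnot(all(c("n_genes", "n_umis", "pct_mito") %in% names(cells)))
  if (any(gene_bounds <= 0) || any(umi_bounds <= 0) ||
      gene_bounds[1] >= gene_bounds[2] || umi_bounds[1] >= umi_bounds[2]) {
    stop_cellqtl("bounds must be positive with min < max")
  }
  cells$n_genes >= gene_bounds[1] & cells$n_genes <= gene_bounds[2] &
    cells$n_umis >= umi_bounds[1] & cells$n_umis <= umi_bounds[2] &
    cells$pct_mito <= mito_max
}

#' Shannon entropy of a cell-type composition
#'
#' `H = -sum_x p_x log2 p_x` with `p_x` the proportion of cell type `x`;
#' zero-count types contribute nothing (0 * log 0 = 0).
#'
#' @param counts Named nonnegative count vector (cells per type).
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(counts) {
  if (any(counts < 0)) stop_cellqtl("counts must be nonnegative")
  total <- sum(counts)
  if (total == 0) stop_cellqtl("at least one nonzero count required")
  p <- counts[counts > 0] / total
  -sum(p * log2(p))
}

#' Observed/expected (R_o/e) tissue enrichment of cell clusters
#'
#' For a cell-type x tissue contingency table, `R_oe[c, t] =
#' observed[c, t] / expected[c, t]` with `expected = row_total * col_total /
#' grand_total`. A value > 1 means the cluster is enriched in that tissue.
#' Cells with expected count 0 are `NA` (undefined, never imputed).
#'
#' @param contingency Nonnegative cell-type x tissue count matrix.
#' @return Matrix of the same shape with the observed/expected ratios.
#' @export
roe_enrichment <- function(contingency) {
  x <- as.matrix(contingency)
  if (any(x < 0)) stop_cellqtl("counts must be nonnegative")
  total <- sum(x)
  if (total == 0) stop_cellqtl("total count must be > 0")
  expected <- outer(rowSums(x), colSums(x)) / total
  r <- x / expected
  r[expected == 0] <- NA_real_
  r
}

#' Cell-cycle index
#'
#' `log10(n_cycling / n_noncycling)`: the log10 ratio of cycling (G1/S/G2/M
#' scored) to noncycling (G0) cells in a cell type. Progenitor-like types score
#' high, quiescent types low. Degenerate inputs (no noncycling cells, or no
#' cycling cells) are undefined and returned as `NA` with a warning.
#'
#' @param n_cycling,n_noncycling Nonnegative cell counts.
#' @return The index, or `NA` when undefined.
#' @export
cell_cycle_index <- function(n_cycling, n_noncycling) {
  if (n_cycling < 0 || n_noncycling < 0) stop_cellqtl("counts must be nonnegative")
  if (n_noncycling == 0) {
    warning("no noncycling cells: cell-cycle index undefined")
    return(NA_real_)
  }
  if (n_cycling == 0) {
    warning("no cycling cells: cell-cycle index is -Inf, returned as NA")
    return(NA_real_)
  }
  log10(n_cycling / n_noncycling)
}

#' Aggregate single-cell counts into pseudo-bulk profiles
#'
#' Sums counts over cells sharing a label. `scale = "cpm"` rescales each
#' aggregated column to 1e6; `"tpm"` first divides by gene length in kb
#' (default 1 kb for every gene, in which case TPM equals CPM) and then
#' rescales to 1e6.
#'
#' @param counts Cells x genes count matrix.
#' @param labels Per-cell grouping labels (cell type or sample).
#' @param scale One of `"counts"`, `"cpm"`, `"tpm"`.
#' @param gene_lengths Optional per-gene lengths in bp (for TPM).
#' @return Genes x groups matrix.
#' @export
pseudo_bulk <- function(counts, labels, scale = c("counts", "cpm", "tpm"),
                        gene_lengths = NULL) {
  scale <- match.arg(scale)
  counts <- as.matrix(counts)
  if (length(labels) != nrow(counts)) {
    stop_cellqtl("labels must have one entry per cell (matrix row)")
  }
  groups <- sort(unique(as.character(labels)))
  agg <- vapply(groups, function(g) colSums(counts[labels == g, , drop = FALSE]),
                numeric(ncol(counts)))
  rownames(agg) <- colnames(counts)
  if (scale == "counts") return(agg)
  if (scale == "tpm") {
    len_kb <- (gene_lengths %||% rep(1000, nrow(agg))) / 1000
    agg <- agg / len_kb
  }
  sweep(agg, 2, colSums(agg), "/") * 1e6
}

# Two-sided Wilcoxon rank-sum p-value with a deterministic tie policy:
# average ranks throughout; exact enumeration of all subsets when
# n1 + n2 <= 20, normal approximation with tie correction and continuity
# correction otherwise. U is symmetric about n1*n2/2 under the null even with
# ties, so the two-sided exact p is the symmetric tail probability.
ranksum_pvalue <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n <= 20L) {
    idx <- combn(n, n1)
    null_u <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    return(mean(abs(null_u - mu) >= abs(u - mu) - 1e-12))
  }
  ties <- table(r)
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
  min(1, 2 * pnorm(-max(z, 0)))
}

#' Rank cell-type marker genes (one-vs-rest Wilcoxon)
#'
#' Library-scales each cell to 10,000 counts, then for every (gene, cell type)
#' tests cells of the type against all other cells with a two-sided Wilcoxon
#' rank-sum test on the log-normalised expression. The log2 fold change is
#' `log2((mean_in + eps) / (mean_out + eps))` on the library-scaled values
#' (eps = 1e-9). P-values are Benjamini-Hochberg adjusted within each cell
#' type. Types with fewer than 2 cells are skipped with a warning.
#'
#' @param counts Cells x genes count matrix.
#' @param labels Per-cell cell-type labels.
#' @return data.frame (`marker_table`) with columns `gene`, `cell_type`,
#'   `log2_fold_change`, `p_value`, `adjusted_p`.
#' @export
rank_markers <- function(counts, labels) {
  counts <- as.matrix(counts)
  labels <- as.character(labels)
  if (length(labels) != nrow(counts)) stop_cellqtl("one label per cell required")
  types <- sort(unique(labels))
  if (length(types) < 2L) stop_cellqtl("need >= 2 cell types")
  lib <- rowSums(counts)
  lib[lib == 0] <- 1
  scaled <- counts / lib * 1e4
  eps <- 1e-9
  out <- vector("list", length(types))
  for (k in seq_along(types)) {
    in_grp <- labels == types[k]
    if (sum(in_grp) < 2L) {
      warning(sprintf("cell type '%s' has < 2 cells: skipped", types[k]))
      next
    }
    mean_in <- colMeans(scaled[in_grp, , drop = FALSE])
    mean_out <- colMeans(scaled[!in_grp, , drop = FALSE])
    pv <- vapply(seq_len(ncol(scaled)), function(j) {
      ranksum_pvalue(scaled[in_grp, j], scaled[!in_grp, j])
    }, numeric(1))
    out[[k]] <- data.frame(
      gene = colnames(scaled), cell_type = types[k],
      log2_fold_change = log2((mean_in + eps) / (mean_out + eps)),
      p_value = pv, adjusted_p = p.adjust(pv, method = "BH"),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  class(res) <- c("marker_table", "data.frame")
  res
}

# deterministic marker ordering: adjusted p ascending, then larger |log2FC|,
# then lexicographic gene id
order_markers <- function(m) {
  m[order(m$adjusted_p, -abs(m$log2_fold_change), m$gene), , drop = FALSE]
}

#' Build a cell-type signature matrix from ranked markers
#'
#' For each cell type, genes with `adjusted_p < padj_max` and
#' `log2_fold_change > lfc_min` are sorted by adjusted p-value (ties broken by
#' larger |log2FC|, then gene id) and the top `top_n` retained. The signature
#' holds the per-type pseudo-bulk TPM values over the union of selected genes.
#' Cell types with no passing gene are dropped with a warning.
#'
#' @param markers A `marker_table` from [rank_markers()].
#' @param pseudo_bulk_tpm Genes x cell types TPM matrix (from [pseudo_bulk()]).
#' @param top_n Markers kept per cell type (default 50).
#' @param padj_max Adjusted p-value ceiling (default 0.05, strict).
#' @param lfc_min log2 fold-change floor (default 0.5, strict).
#' @return A `signature_matrix`: genes x cell types numeric matrix with a
#'   `selected_markers` attribute (named list per type).
#' @export
build_signature_matrix <- function(markers, pseudo_bulk_tpm, top_n = 50,
                                   padj_max = 0.05, lfc_min = 0.5) {
  if (nrow(markers) == 0L) stop_cellqtl("markers must be non-empty")
  tpm <- as.matrix(pseudo_bulk_tpm)
  types <- sort(unique(markers$cell_type))
  selected <- list()
  for (ct in types) {
    m <- markers[markers$cell_type == ct &
                   markers$adjusted_p < padj_max &
                   markers$log2_fold_change > lfc_min, , drop = FALSE]
    if (nrow(m) == 0L) {
      warning(sprintf("cell type '%s' has no passing markers: excluded", ct))
      next
    }
    m <- order_markers(m)
    selected[[ct]] <- head(m$gene, top_n)
  }
  if (length(selected) == 0L) stop_cellqtl("no cell type has passing markers")
  genes <- sort(unique(unlist(selected)))
  missing <- setdiff(genes, rownames(tpm))
  if (length(missing) > 0L) {
    stop_cellqtl("pseudo-bulk matrix lacks selected genes: ",
                 paste(head(missing, 5), collapse = ", "))
  }
  sig <- tpm[genes, names(selected), drop = FALSE]
  structure(sig, class = c("signature_matrix", class(sig)),
            selected_markers = selected)
}
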
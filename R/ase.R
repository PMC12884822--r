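#' Allelic imbalance
#'
#' `AI = |ref_reads / total_reads - 0.5|`: 0 for perfectly balanced
#' expression, 0.5 for monoallelic expression.
#'
#' @param ref_reads Reference-haplotype read counts.
#' @param total_reads Total read counts (>= 1).
#' @return AI values in \[0, 0.5\].
#' @export
allelic_imbalance <- function(ref_reads, total_reads) {
  if (any(total_reads < 1)) stop_cellqtl("total_reads must be >= 1")
  abs(ref_reads / total_reads - 0.5)
}

#' Hampel/MAD outlier filter
#'
#' Flags value i iff `|x_i - median(x)| >= k * MAD` with the unscaled
#' `MAD = median(|x_i - median(x)|)` (no 1.4826 consistency constant). When
#' MAD = 0 the rule degenerates, and any value different from the median is
#' flagged instead.
#'
#' @param values Numeric vector (>= 3 values).
#' @param k Threshold multiplier (default 4.5).
#' @return Logical vector, `TRUE` = outlier.
#' @export
mad_outlier_filter <- function(values, k = 4.5) {
  if (length(values) < 3L) stop_cellqtl("need at least 3 values")
  med <- median(values)
  dev <- abs(values - med)
  m <- median(dev)
  if (m > 0) dev >= k * m else values != med
}

#' Per-individual allelic fold change
#'
#' `aFC = log2((alt + pseudocount) / (ref + pseudocount))` from
#' haplotype-specific read counts. The pseudocount keeps zero-coverage sites
#' defined (0, 0 maps to 0).
#'
#' @param ref_hap_reads,alt_hap_reads Nonnegative haplotype read counts.
#' @param pseudocount Added to both counts (default 1).
#' @return aFC in log2 units; sign flips when ref/alt are swapped.
#' @export
estimate_afc <- function(ref_hap_reads, alt_hap_reads, pseudocount = 1) {
  if (any(ref_hap_reads < 0) || any(alt_hap_reads < 0)) {
    stop_cellqtl("read counts must be nonnegative")
  }
  log2((alt_hap_reads + pseudocount) / (ref_hap_reads + pseudocount))
}

#' Validate an ieQTL with allele-specific expression
#'
#' For one (gene, SNP, cell type): keeps heterozygous individuals with total
#' reads strictly above `min_reads`, removes Hampel/MAD outliers on the
#' allelic-imbalance values, and requires strictly more than `min_het`
#' individuals to remain (otherwise `not_testable`). The ieQTL is `validated`
#' iff the two-sided Pearson correlation between per-individual aFC and
#' cell-type enrichment is significant at `p < alpha`.
#'
#' @param records data.frame with `ref_hap_reads`, `alt_hap_reads`,
#'   `enrichment`, and optionally `is_het` (default all heterozygous).
#' @param min_het Minimum surviving heterozygous individuals (strict; default 10).
#' @param min_reads Minimum total reads per individual (strict; default 8).
#' @param mad_k Hampel multiplier (default 4.5).
#' @param alpha Significance level (default 0.05).
#' @return List with `status` (`validated` / `not_validated` /
#'   `not_testable`), `n_used`, `pearson_r`, `p_value`.
#' @export
validate_ieqtl_with_ase <- function(records, min_het = 10, min_reads = 8,
                                    mad_k = 4.5, alpha = 0.05) {
  het <- if ("is_het" %in% names(records)) records$is_het else TRUE
  total <- records$ref_hap_reads + records$alt_hap_reads
  keep <- het & total > min_reads
  rec <- records[keep, , drop = FALSE]
  if (nrow(rec) >= 3L) {
    ai <- allelic_imbalance(rec$ref_hap_reads,
                            rec$ref_hap_reads + rec$alt_hap_reads)
    rec <- rec[!mad_outlier_filter(ai, k = mad_k), , drop = FALSE]
  }
  if (nrow(rec) <= min_het) {
    return(list(status = "not_testable", n_used = nrow(rec),
                pearson_r = NA_real_, p_value = NA_real_))
  }
  afc <- estimate_afc(rec$ref_hap_reads, rec$alt_hap_reads)
  if (sd(afc) == 0 || sd(rec$enrichment) == 0) {
    return(list(status = "not_validated", n_used = nrow(rec),
                pearson_r = NA_real_, p_value = NA_real_))
  }
  r <- cor(afc, rec$enrichment)
  df <- nrow(rec) - 2L
  p <- if (abs(r) >= 1) 0 else 2 * pt(-abs(r * sqrt(df / (1 - r^2))), df)
  list(status = if (p < alpha) "validated" else "not_validated",
       n_used = nrow(rec), pearson_r = r, p_value = p)
}
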
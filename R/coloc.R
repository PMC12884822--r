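#' Select GWAS loci for colocalization
#'
#' A gene's locus is the set of GWAS SNPs within `window` of its TSS; the
#' locus is retained iff its minimum p-value is below `p_threshold`. With
#' `genes = NULL` the whole summary table is treated as one locus.
#'
#' @param gwas Summary data.frame with `snp`, `chrom`, `pos`, `p`.
#' @param p_threshold Retention threshold (default 1e-5, strict).
#' @param genes Optional gene-model data.frame (`gene_id`, `chrom`, `tss`).
#' @param window Cis-window half-width (default 1e6).
#' @return Named list of retained loci (data.frame subsets of `gwas`); empty
#'   list when nothing passes.
#' @export
select_gwas_loci <- function(gwas, p_threshold = 1e-5, genes = NULL,
                             window = 1e6) {
  if (is.null(genes)) {
    if (min(gwas$p) < p_threshold) return(list(locus = gwas))
    return(list())
  }
  loci <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    sel <- gwas$chrom == g$chrom & abs(gwas$pos - g$tss) <= window
    if (any(sel) && min(gwas$p[sel]) < p_threshold) {
      loci[[g$gene_id]] <- gwas[sel, , drop = FALSE]
    }
  }
  loci
}

#' Wakefield approximate log Bayes factor
#'
#' With `V = se^2`, `W = prior_sd^2`, `r = W / (V + W)` and `z = beta / se`:
#' `log ABF = 0.5 * log(1 - r) + 0.5 * r * z^2`, the log Bayes factor for
#' association of one SNP against the null under a `N(0, W)` effect prior.
#'
#' @param beta Effect estimates.
#' @param se Standard errors (> 0).
#' @param prior_sd Prior standard deviation of the (standardized) effect
#'   (default 0.15).
#' @return Log Bayes factors (vectorised).
#' @export
wakefield_log_abf <- function(beta, se, prior_sd = 0.15) {
  if (prior_sd <= 0) stop_cellqtl("prior_sd must be > 0")
  if (any(se <= 0)) stop_cellqtl("se must be > 0")
  r <- prior_sd^2 / (se^2 + prior_sd^2)
  z <- beta / se
  0.5 * log(1 - r) + 0.5 * r * z^2
}

#' Approximate-Bayes-factor colocalization (PP0-PP4)
#'
#' Harmonises the two traits by SNP id and computes the posterior
#' probabilities of the five causal configurations: H0 no association, H1/H2
#' association with one trait only, H3 two distinct causal variants, H4 one
#' shared causal variant. Per-hypothesis evidence is accumulated in log space
#' (log-sum-exp), so arbitrarily large z-scores do not overflow.
#'
#' @param trait1,trait2 Summary data.frames with `snp`, `beta`, `se`.
#' @param p1,p2 Prior probability a SNP is causal for trait 1 / trait 2
#'   (defaults 1e-4).
#' @param p12 Prior probability a SNP is causal for both (default 1e-5).
#' @param prior_sd Effect prior passed to [wakefield_log_abf()].
#' @return A `coloc_result` list: `pp0`..`pp4`, `n_snps`, `priors`.
#' @export
coloc_abf <- function(trait1, trait2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      prior_sd = 0.15) {
  shared <- intersect(trait1$snp, trait2$snp)
  if (length(shared) < 2L) stop_cellqtl("need >= 2 shared SNPs after harmonization")
  t1 <- trait1[match(shared, trait1$snp), ]
  t2 <- trait2[match(shared, trait2$snp), ]
  l1 <- wakefield_log_abf(t1$beta, t1$se, prior_sd)
  l2 <- wakefield_log_abf(t2$beta, t2$se, prior_sd)
  s1 <- logsumexp(l1)                 # log sum_i ABF1_i
  s2 <- logsumexp(l2)
  s12 <- logsumexp(l1 + l2)           # log sum_i ABF1_i * ABF2_i
  lh <- c(
    h0 = 0,
    h1 = log(p1) + s1,
    h2 = log(p2) + s2,
    h3 = log(p1) + log(p2) + logdiffexp(s1 + s2, s12),
    h4 = log(p12) + s12
  )
  pp <- exp(lh - logsumexp(lh))
  structure(list(pp0 = pp[["h0"]], pp1 = pp[["h1"]], pp2 = pp[["h2"]],
                 pp3 = pp[["h3"]], pp4 = pp[["h4"]],
                 n_snps = length(shared),
                 priors = c(p1 = p1, p2 = p2, p12 = p12)),
            class = "coloc_result")
}

#' Call significant colocalization
#'
#' @param result A `coloc_result` from [coloc_abf()].
#' @param pp4_min PP4 threshold (default 0.5, strict).
#' @return `TRUE` iff `pp4 > pp4_min`.
#' @export
call_colocalized <- function(result, pp4_min = 0.5) {
  result$pp4 > pp4_min
}
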
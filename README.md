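# cellqtl

Cell-type interaction eQTL mapping with single-cell-informed deconvolution,
in R.

Bulk RNA-seq averages expression over a mixture of cell types, so a
regulatory variant acting in one cell type can be diluted past detection in
standard eQTL scans. `cellqtl` is for analysts who have (i) a labelled
single-cell or single-nucleus reference and (ii) bulk expression with
genotypes, and who want to know *in which cell type* a variant acts. It
implements the whole route:

1. **Signature construction** — one-vs-rest Wilcoxon marker ranking on
   labelled single-cell counts, top-50 markers per type (adjusted p < 0.05,
   log2FC > 0.5), per-type pseudo-bulk TPM signature matrix. Atlas
   composition statistics (Shannon entropy, observed/expected tissue
   enrichment R_o/e, cell-cycle index, QC filters) are included.
2. **Deconvolution** — per-sample cell-type fractions by NNLS (default,
   deterministic) or linear nu-SVR (the CIBERSORT scheme), with a
   permutation significance test and the two-arm eligibility rule
   (fraction > 0 in ≥ 20 samples and/or ≥ 20% of samples).
3. **ieQTL mapping** — for each gene, SNP and cell type, ordinary least
   squares on

   ```
   y ~ g + b + g×b + A
   ```

   (y: inverse-normal-transformed TMM expression; g: dosage 0/1/2; b:
   cell-type enrichment; A: covariates), testing the interaction
   coefficient; ±1 Mb cis window, interaction MAF ≥ 0.05 in both
   enrichment-sorted halves, eigenMT gene-level correction, BH FDR < 0.05
   across genes → ieGenes.
4. **ASE validation** — per-individual allelic fold change
   log2((alt+1)/(ref+1)) at heterozygotes with > 8 reads, Hampel/MAD outlier
   removal on allelic imbalance (unscaled MAD, k = 4.5), validated iff the
   Pearson correlation between aFC and enrichment has p < 0.05 across > 10
   individuals.
5. **Colocalization** — Wakefield approximate Bayes factors and posterior
   probabilities PP0–PP4 of the five causal configurations; loci with a GWAS
   SNP at p < 1e-5; colocalized iff PP4 > 0.5.
6. **Trait enrichment** — Fisher's exact enrichment of genome-wide
   significant variants (p < 5e-8) in ±10 kb regions around each cell type's
   top-200 marker genes, and stratified heritability partitioning
   (no-LD LD-score regression with block-jackknife SEs; enrichment = share
   of h² / share of SNPs).

A synthetic-data module generates every input — negative-binomial
single-cell counts with planted markers, Dirichlet bulk mixtures, Hardy–
Weinberg genotypes (VCF), interaction phenotypes, binomial haplotype ASE
counts, paired GWAS/eQTL summary statistics, chi-square statistics with
planted heritability enrichment — so the full pipeline runs end to end with
known ground truth and no downloads.

## Worked example

Simulate a complete study (one planted ieQTL: gene0040 × snp00020 × type01)
and run the pipeline:

```r
library(cellqtl)

cfg <- sim_config(n_cell_types = 3, n_genes = 80, cells_per_type = 40,
                  n_bulk_samples = 500, n_snps = 40, seed = 1,
                  maf_range = c(0.3, 0.5),
                  effect_sizes = c(beta_g = 0.3, beta_b = 0.5, beta_gxb = 1.5))
st <- simulate_study("demo_study", cfg)
run_pipeline(pipeline_config("demo_study", "demo_out"))
#> [signature] 31 records -> markers.tsv, signature.tsv
#> [deconvolve] 500 records -> fractions.tsv
#> [ieqtl] 80 records -> ieqtl.tsv
#> [ase] 1 records -> ase_validation.tsv
#> [coloc] 1 records -> coloc.tsv
#> [enrich] 3 records -> enrichment.tsv

ie <- read_tsv("demo_out/ieqtl.tsv")
subset(ie, ie_gene, select = c(gene_id, snp_id, beta_gxb, p_nominal, p_eigenmt, fdr))
#>   gene_id   snp_id  beta_gxb    p_nominal    p_eigenmt          fdr
#>  gene0040 snp00020 0.2417783 2.633416e-08 1.053367e-06 8.426932e-05

read_tsv("demo_out/ase_validation.tsv")
#>   gene_id   snp_id n_used pearson_r      p_value    status
#>  gene0040 snp00020    230 0.7257645 6.637567e-39 validated
```

The planted ieQTL is recovered exactly: the focal gene's top SNP is the
planted causal variant, it survives eigenMT + BH correction (fdr = 8.4e-5),
its allelic fold change correlates with the cell-type enrichment across 230
heterozygous individuals (ASE-validated), and the simulated shared-causal
GWAS locus colocalizes with PP4 ≈ 1. Deconvolved type01 fractions correlate
with the planted truth at r = 0.984.

Individual stages are plain functions (`rank_markers`,
`build_signature_matrix`, `deconvolve`, `map_ieqtl`,
`validate_ieqtl_with_ase`, `coloc_abf`, `fisher_enrichment`,
`sldsc_enrichment`, ...) usable on your own TSV/VCF/MatrixMarket files; see
the methods vignette (`vignettes/cellqtl-methods.Rmd`) for the statistical
details and design choices.

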
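---
title: "Methods: cell-type interaction eQTL mapping with single-cell-informed deconvolution"
author: "cellqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-type interaction eQTL mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellqtl)
```

# Overview

Bulk RNA-seq averages expression over a mixture of cell types, so a variant
whose regulatory effect is confined to one cell type can be invisible to
standard eQTL mapping. `cellqtl` implements the single-cell-informed route
around this problem:

1. build a **signature matrix** of cell-type-specific marker expression from
   labelled single-cell/nucleus counts;
2. **deconvolute** bulk samples against that signature to obtain per-sample
   cell-type fractions (enrichment scores $b$);
3. map **cell-type interaction eQTL (ieQTL)** by testing the
   genotype-by-enrichment interaction in the linear model
   $y \sim g + b + g{\times}b + A$;
4. **validate** ieQTL with allele-specific expression (ASE);
5. **colocalize** ieQTL with GWAS loci via approximate Bayes factors;
6. associate cell types with complex traits by **Fisher-exact variant
   enrichment** and **stratified heritability partitioning**.

Every stage is exercised end to end on synthetic data with planted ground
truth, generated by the package itself, so the whole pipeline is testable
without any external download.

# The interaction model

For one gene, one SNP and one cell type, the package fits by ordinary least
squares

$$ y_i = \beta_0 + \beta_g g_i + \beta_b b_i + \beta_{g\times b}\, g_i b_i
   + A_i \gamma + \varepsilon_i, $$

where $y$ is the expression phenotype (conventionally TMM-normalised and then
rank-based inverse-normal transformed), $g \in \{0,1,2\}$ the allelic dosage,
$b$ the cell-type enrichment score (also inverse-normal transformed before
fitting, mirroring common ieQTL practice), and $A$ optional covariates. The
reported test is the two-sided $t$-test on $\hat\beta_{g\times b}$ with
$n - \mathrm{rank}$ degrees of freedom. An ieQTL is a SNP whose interaction
term survives multiple-testing correction; an **ieGene** is a gene with at
least one such SNP at FDR < 0.05.

The scan tests every SNP within a closed $\pm$1 Mb window of the gene's TSS.
Before fitting, a SNP must pass the **interaction MAF filter**: samples are
sorted by $b$ and the allele frequency must lie in $[0.05, 0.95]$ in *both*
the top and the bottom half (with odd $n$, the middle sample joins the bottom
half — a fixed, documented convention). This prevents interaction estimates
driven by a handful of carriers concentrated at one end of the enrichment
distribution.

Gene-level correction uses the effective number of independent tests
(**eigenMT**): the SNP-SNP Pearson correlation matrix of the cis window is
eigendecomposed in non-overlapping blocks of 200 SNPs, and $M_\mathrm{eff}$
is the summed minimal number of eigenvalues explaining 99% of each block's
variance; the gene's top nominal p-value is multiplied by $M_\mathrm{eff}$
and capped at 1. Benjamini–Hochberg FDR is then applied across genes within
each tissue-cell-type group. The 0.99 threshold and 200-SNP window follow the
standard defaults for this correction.

# Deconvolution

The signature matrix holds per-type pseudo-bulk TPM over the union of
selected markers (gene lengths default to 1 kb, making TPM equal CPM, since
the synthetic data carry no length information). Markers come from a
one-vs-rest two-sided Wilcoxon rank-sum test on library-scaled (10,000 counts
per cell) expression, with BH adjustment within cell type; per type, genes
with adjusted $p < 0.05$ and $\log_2\mathrm{FC} > 0.5$ are ranked by adjusted
p (ties: larger $|\log_2\mathrm{FC}|$, then gene id) and the top 50 kept.

The rank-sum test uses a deterministic policy: average ranks for ties, exact
enumeration of all $\binom{n}{n_1}$ label assignments when $n \le 20$, and
the normal approximation with tie and continuity corrections otherwise. The
two-sided exact p-value is the symmetric tail of the Mann–Whitney $U$
statistic, which remains symmetric about $n_1 n_2 / 2$ under ties.

For a bulk sample the package estimates nonnegative mixing weights of the
signature columns and normalises them to sum to 1. Two solvers are exposed:

- **NNLS** (default): deterministic, exact on noiseless mixtures;
- **nu-SVR**: linear $\nu$-support-vector regression over
  $\nu \in \{0.25, 0.5, 0.75\}$, keeping the lowest-RMSE fit and clipping
  negative coefficients — the scheme popularised by signature-based
  deconvolution tools. NNLS is the default because $\nu$-SVR solutions vary
  across solver implementations while NNLS is reproducible bit for bit.

Before fitting, the bulk vector is z-scored and the signature is z-scored as
a whole matrix; both are then mean-centred (the bulk, and each signature
column). Centring makes the per-column intercepts cancel, so a noiseless
mixture is an *exact* nonnegative combination of the processed columns and
true fractions are recovered to machine precision — a property the test
suite asserts at $10^{-6}$. Fit quality is summarised by the Pearson $r$ and
RMSE of the reconstruction, and significance by a permutation test (gene
labels of the bulk vector shuffled, default 1000 permutations, add-one
estimator so $p > 0$).

The "enrichment score" $b$ carried into ieQTL mapping is the normalised
fraction itself. The upstream literature is ambiguous between raw fractions
and scaled scores; since $b$ is inverse-normal transformed before fitting and
the interaction $t$-statistic is invariant to affine rescaling of $b$, the
choice does not affect ieQTL calls.

A cell type is **eligible** for mapping if its fraction is positive in at
least 20 samples *or* in at least 20% of samples.

# ASE validation

For the top ieQTL of an ieGene, heterozygous individuals with more than 8
haplotype-resolved reads are collected; allelic imbalance
$\mathrm{AI} = |\mathrm{ref}/\mathrm{total} - 0.5|$ is screened with a
Hampel/MAD filter (flag iff $|AI_i - \mathrm{median}| \ge 4.5 \times
\mathrm{MAD}$, with the *unscaled* MAD — no 1.4826 consistency constant —
and, when MAD $= 0$, any value off the median flagged). If more than 10
individuals remain, the per-individual allelic fold change
$\mathrm{aFC} = \log_2\frac{\mathrm{alt} + 1}{\mathrm{ref} + 1}$ is
correlated with the individual's cell-type enrichment; the ieQTL is
*validated* iff the two-sided Pearson test gives $p < 0.05$. The pseudocount
log-ratio is a deliberate, simple per-individual effect-size estimate; the
model-based haplotype estimator used by phasing tools is not re-implemented,
because only a per-locus effect size to correlate with enrichment is needed.

# Colocalization

Per SNP and trait, the Wakefield approximate log Bayes factor is
$\tfrac12\log(1-r) + \tfrac12 r z^2$ with $r = W/(V+W)$, $V = \mathrm{se}^2$,
$W = 0.15^2$. Hypothesis evidence (H0 none; H1/H2 one trait; H3 two distinct
causal variants; H4 one shared) is accumulated in log space with
log-sum-exp, so $|z|$ up to several hundred cannot overflow. Priors are the
conventional defaults $p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$. Loci enter
colocalization when at least one GWAS SNP has $p < 10^{-5}$; a pair is called
colocalized when $\mathrm{PP4} > 0.5$ (strict). Effects are assumed
standardized (se $\approx 1/\sqrt{n}$); the prior sd is an exposed argument
for users whose summary statistics are on other scales. Harmonisation is by
SNP id only — appropriate for the synthetic data, which controls strand.

A useful limiting property, asserted in the tests: if one trait's SEs are
inflated to uselessness its per-SNP Bayes factors tend to 1, the
joint-signal hypotheses H2/H3 vanish, and the posterior mass splits between
H0/H1/H4 with $\mathrm{PP4}/\mathrm{PP1} \to p_{12}/p_1$. The residual PP4
share is a prior artefact, not evidence of sharing.

# Trait enrichment and heritability partitioning

For each cell type, the top 200 markers by ascending p-value anchor
$\pm$10 kb TSS intervals; genome-wide-significant GWAS variants
($p < 5\times10^{-8}$) are tested for membership enrichment against all
tested SNPs with a two-sided Fisher's exact test (odds ratio $ad/bc$,
Haldane 0.5 only when a cell is zero), BH-corrected across annotation-trait
pairs. Regions are TSS-anchored flanks rather than gene bodies, for symmetry
with the $\pm$10 kb heritability rule; both conventions are arguments.

Heritability partitioning fits
$\mathrm{E}[\chi^2_j] = N \sum_c \tau_c\, \ell(j, c) + a$ by one-step
reweighted least squares (weights $1/(2\,\hat{\mathrm{E}}[\chi^2_j]^2)$, the
chi-square variance), with a free intercept and a delete-one block jackknife
(20 contiguous blocks, a small-scale analogue of the standard 200) for the
coefficient $z$ and the enrichment SE. The package operates in a **no-LD
regime**: for unlinked SNPs the LD score of SNP $j$ in annotation $c$ is its
membership indicator, per-SNP heritability is the $\tau$-weighted membership
sum, and enrichment is $(\mathrm{h}^2_c/\mathrm{h}^2)\,/\,(M_c/M)$.
User-supplied LD scores are accepted but never computed from a reference
panel. Two numerical consequences are handled explicitly:

- a base annotation covering all SNPs has a *constant* LD-score column,
  exactly collinear with the free intercept; the fit absorbs it and recovers
  $\tau_\mathrm{base} = (\hat a - 1)/N$ (without confounding the expected
  intercept is 1 — confounding and base polygenicity are not separable in
  this regime, a documented limitation);
- overlapping annotations can make the design rank deficient (e.g. two
  columns summing to the base); non-estimable coefficients are gauge-fixed
  to 0, which leaves per-SNP heritability — and hence all reported
  proportions and enrichments — invariant.

Block jackknife assumes the annotation is spread across blocks; an
annotation confined to one or two contiguous blocks (unlike real cell-type
gene sets, which scatter over the genome) yields unreliable SEs.

# The synthetic-data generators

The generators are first-class, tested code, and their defaults define the
study conditions the test suite measures:

- **Single-cell counts**: negative binomial with dispersion 0.5 (variance
  $\mu + 0.5\mu^2$), lognormal per-gene baseline means, and per-type marker
  genes elevated 8-fold — overdispersion the marker test must tolerate.
- **Bulk mixtures**: Dirichlet fractions times the signature, with
  *multiplicative* lognormal noise $\exp N(0, \sigma^2)$ so TPM-like
  positivity is preserved (an additive model could go negative).
- **Genotypes**: Binomial(2, $f$) with $f \sim U(\mathrm{maf\ range})$,
  unlinked, on one synthetic chromosome at 1 kb spacing (1-based); an
  optional block-copy mode creates perfect-LD blocks for eigenMT tests.
- **ASE counts**: alt reads $\sim$ Binomial(depth, $\pi_i$) with
  $\log_2 \pi_i/(1-\pi_i) = \mathrm{aFC} \cdot b_i$. The logit-linear link in
  the cell fraction is a modelling choice (no generative model is standard
  here); it makes the aFC-enrichment correlation criterion recoverable by
  construction.
- **Summary-statistic pairs**: z-scores $N(0,1)$ at non-causal SNPs and
  noncentrality $\mathrm{effect}\cdot\sqrt{n}$ at causal ones, with shared /
  distinct / null causal configurations; $\mathrm{se} = 1/\sqrt n$ on the
  standardized scale.
- **Chi-square statistics**: $z_j \sim N(0, 1 + N h^2_j)$ with per-SNP
  heritability split so the annotation carries a chosen share — the no-LD
  expectation of the partitioning model.

What the generators do **not** emulate: linkage disequilibrium from a
recombination map, doublets and ambient RNA, read-level sequences,
batch effects, and population structure. Passing the closed-loop tests
therefore demonstrates correctness of the statistical machinery under its
own assumptions, not robustness to the full messiness of real data.

## The planted-ieQTL study (`simulate_study`)

The end-to-end smoke study writes every pipeline input to disk with one
focal gene carrying a planted interaction: its bulk profile is
$\exp(y)$ with $y$ drawn from the interaction model on the log scale
($\beta_{g\times b} = 1.5$, residual sd 0.5 in the smoke studies), the causal
SNP is the
one nearest the focal TSS, and the interacting type is the first cell type.
The smoke tests use 500 bulk samples with common variants (MAF 0.3–0.5).
These values keep the phenotype near-normal, which matters: the rank-based
inverse normal transform is nearly affine on a near-normal phenotype but
*compresses the signal-carrying tail* of a strongly skewed one. Empirically,
a planted effect of $\beta_{g\times b} = 3$ at residual sd 1 gives a raw-scale
interaction $t \approx 6.4$ that collapses to $t \approx 2.2$ after the
transform, while the modest-effect design retains its power. Real eQTL
effects are a small share of phenotype variance, which is why the transform
is harmless in practice.

## On "standardized" interaction effects

The power analyses specify a standardized interaction effect of 0.5. The
package interprets this as effect per standard deviation of the interaction
term's **unique** variation — the residual of $g b$ on $\{1, g, b\}$ — in
residual-sd units, because that is the quantity the $t$-test on
$\beta_{g\times b}$ actually measures. ($g b$ is strongly collinear with $g$
and $b$; standardizing against its marginal sd would conflate effect size
with collinearity.)

# Problem sizes and numerical choices

The test suite runs at deliberately desk-scale sizes: single-cell references
of 3 types $\times$ 120–150 genes $\times$ 40–60 cells/type; 1000 pseudo-bulk
mixtures for deconvolution recovery; 1000 null refits and 100 powered
replicates (n = 300) for the interaction test; 200 permutation-null mini
studies for FDR control; 100 replicates each for ASE validation and the two
coloc scenarios (200 SNPs, per-trait n = 10,000); 100 replicates of
heritability partitioning at M = 5,000 SNPs, N = 50,000. The whole suite
completes in under a minute on one CPU; the acceptance script recomputes the
headline quantities in a few seconds.

Other fixed numerical conventions: dosage missing values are mean-imputed
per SNP before fitting; constant SNP columns are excluded from eigenMT
correlation (all-constant windows give $M_\mathrm{eff} = 1$); the
inverse-normal transform uses offset ranks $(\mathrm{rank} - 0.5)/n$ with
average ranks for ties and refuses constant input; `cell_cycle_index`
returns `NA` with a warning for its two undefined edges (no noncycling, or
no cycling, cells); QC bounds are inclusive because the source thresholds
are phrased as strict exclusions ("fewer than 200 genes"); all generators
are pure functions of (configuration, seed) and restore the caller's RNG
state.

# Known limitations

- Deconvolution assumes the signature spans the cell types actually present;
  missing types bias fractions upward for similar present types.
- The no-LD heritability regime cannot separate confounding from base
  polygenicity (both live in the intercept) and its enrichment SEs rely on
  the block-jackknife exchangeability assumption.
- ASE validation uses a pseudocounted read-ratio aFC, not a model-based
  haplotype estimator; with very low depth it is shrunk toward 0.
- Colocalization assumes a single causal variant per trait per locus and
  standardized effects; multi-signal loci require fine-mapping-aware methods
  out of scope here.
- Covariate sets (genotype PCs, expression latent factors) are user-supplied;
  the package does not estimate latent factors.
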
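Package: cellqtl
Title: Cell-Type Interaction eQTL Mapping with Single-Cell-Informed Deconvolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A single-cell-informed genetic analysis pipeline for bulk tissues:
    builds cell-type signature matrices from labelled single-cell counts, estimates
    per-sample cell-type fractions by signature-based deconvolution (non-negative
    least squares or linear nu-support-vector regression with permutation
    significance), maps cell-type interaction cis-eQTL (ieQTL) with a genotype-by-
    cell-fraction linear interaction model followed by eigenMT and Benjamini-Hochberg
    correction, validates ieQTL with allele-specific expression (allelic fold change,
    Hampel/MAD outlier filtering, correlation with cell-type enrichment), colocalizes
    ieQTL with GWAS loci via Wakefield approximate Bayes factors (PP0-PP4), and
    associates cell types with complex traits through Fisher-exact variant enrichment
    and stratified heritability partitioning. A synthetic-data module generates every
    input with planted ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    withr,
    pracma,
    e1071,
    edgeR,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
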
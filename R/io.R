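# Plain-text readers/writers for every interchange format the pipeline uses:
# MatrixMarket single-cell counts, genes x samples expression TSV, minimal
# VCFv4.2 genotypes, TSS-anchored gene models (BED4 + strand), GWAS/eQTL
# summary TSV, ASE TSV and ground-truth JSON.

#' Write a single-cell count reference to disk
#'
#' Writes `matrix.mtx` (genes x cells, MatrixMarket), `genes.tsv` and
#' `cells.tsv` into `dir`.
#'
#' @param ref List from [simulate_single_cell_reference()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_single_cell_reference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(t(ref$counts), sparse = TRUE)   # genes x cells
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(colnames(ref$counts), file.path(dir, "genes.tsv"))
  write.table(ref$cells, file.path(dir, "cells.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a single-cell count reference
#'
#' @param dir Directory holding `matrix.mtx`, `genes.tsv`, `cells.tsv`.
#' @return List with `counts` (cells x genes dense matrix) and `cells`.
#' @export
read_single_cell_reference <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  genes <- readLines(file.path(dir, "genes.tsv"))
  cells <- read.delim(file.path(dir, "cells.tsv"), stringsAsFactors = FALSE)
  counts <- t(m)
  dimnames(counts) <- list(cells$cell_id, genes)
  list(counts = counts, cells = cells)
}

#' Write a genes x samples expression matrix as TSV
#' @param mat Numeric matrix with gene row names.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genes x samples expression TSV
#' @param path File written by [write_expression_tsv()].
#' @return Numeric matrix with gene row names.
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}

#' Write genotype dosages as a minimal VCFv4.2 (GT only)
#' @param genotypes A `genotype_matrix`.
#' @param path Output file (plain text).
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(genotypes$dosages)),
                    collapse = "\t"))
  body <- vapply(seq_len(nrow(genotypes$snps)), function(j) {
    g <- genotypes$dosages[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    paste(c(genotypes$snps$chrom[j], genotypes$snps$pos[j],
            genotypes$snps$id[j], "A", "G", ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotype dosages from a VCF (GT field)
#'
#' Dosage is the count of alternative alleles in GT (0/1/2; missing -> NA).
#'
#' @param path VCF file.
#' @return A `genotype_matrix`.
#' @export
read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")    # snps x samples
  alt_count <- vapply(strsplit(gsub("\\|", "/", as.vector(gt)), "/"),
                      function(a) if (length(a) == 0L || anyNA(a) || any(a == "."))
                                    NA_integer_ else sum(a == "1"), integer(1))
  dos <- matrix(alt_count, nrow = ncol(gt), byrow = TRUE,
                dimnames = list(colnames(gt), rownames(gt)))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  structure(list(
    dosages = dos,
    snps = data.frame(id = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS),
                      stringsAsFactors = FALSE)),
    class = "genotype_matrix")
}

#' Write gene models as BED4 + strand
#'
#' One zero-based half-open single-base interval per TSS:
#' `chrom, tss - 1, tss, gene_id, strand`.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `tss`, optional `strand`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gene_models_bed <- function(genes, path) {
  strand <- genes$strand %||% rep("+", nrow(genes))
  write.table(data.frame(genes$chrom, genes$tss - 1L, genes$tss,
                         genes$gene_id, strand),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read gene models from BED4 + strand
#' @param path BED file from [write_gene_models_bed()].
#' @return data.frame with `gene_id`, `chrom`, `tss` (1-based), `strand`.
#' @export
read_gene_models_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(gene_id = df[[4]], chrom = as.character(df[[1]]),
             tss = df[[3]], strand = if (ncol(df) >= 5) df[[5]] else "+",
             stringsAsFactors = FALSE)
}

#' Write / read a generic TSV table
#' @param df data.frame.
#' @param path File path.
#' @return `path` (write) or data.frame (read).
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
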
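#' Simulate a complete study to disk
#'
#' Generates a coherent synthetic study and writes every pipeline input:
#' labelled single-cell counts (MatrixMarket + TSVs), bulk mixtures built
#' from the true per-type expression profiles, genotypes (VCFv4.2), gene
#' models (BED), haplotype-specific ASE counts, paired GWAS/eQTL summary
#' statistics and a ground-truth JSON. One focal gene carries a planted
#' interaction eQTL: its bulk profile follows the genotype x cell-fraction
#' interaction model on the log scale, with the SNP nearest its TSS as the
#' causal variant and the first cell type as the interacting type.
#'
#' @param out_dir Output directory.
#' @param cfg A [sim_config()]; its `seed` drives every draw.
#' @param preset Which inputs to write: `"full"` (everything; default) or a
#'   subset `"decon"`, `"ieqtl"`, `"ase"`, `"coloc"`, `"ldsc"`.
#' @param gwas_scenario Causal configuration of the paired summary statistics.
#' @param ieqtl_noise_sd Residual standard deviation of the planted
#'   interaction phenotype on the log scale (default 0.5; the phenotype stays
#'   near-normal so the rank-based inverse normal transform applied downstream
#'   is close to affine).
#' @return Invisibly, a list with the ground truth and file paths.
#' @export
simulate_study <- function(out_dir, cfg = sim_config(),
                           preset = c("full", "decon", "ieqtl", "ase",
                                      "coloc", "ldsc"),
                           gwas_scenario = "shared", ieqtl_noise_sd = 0.5) {
  preset <- match.arg(preset)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  want <- function(x) preset %in% c("full", x)
  paths <- list()

  ref <- simulate_single_cell_reference(cfg)
  if (want(c("decon", "ieqtl"))) {
    paths$single_cell <- write_single_cell_reference(ref, file.path(out_dir, "sc"))
  }

  # true per-type expression profile on TPM scale
  sig_true <- pseudo_bulk(ref$counts, ref$cells$cell_type, scale = "tpm")
  mix <- simulate_bulk_mixtures(sig_true, cfg$n_bulk_samples,
                                cfg$dirichlet_alpha, cfg$bulk_noise_sd,
                                seed = cfg$seed + 1L)
  geno <- simulate_genotypes(cfg$n_bulk_samples, cfg$n_snps, cfg$maf_range,
                             seed = cfg$seed + 2L)

  # plant one ieQTL: focal gene, SNP nearest the TSS, first cell type
  genes <- data.frame(gene_id = rownames(sig_true), chrom = "1",
                      tss = round(seq(1, max(geno$snps$pos, 2), # nolint
                                      length.out = nrow(sig_true))),
                      strand = "+", stringsAsFactors = FALSE)
  focal_gene <- genes$gene_id[ceiling(nrow(genes) / 2)]
  focal_tss <- genes$tss[genes$gene_id == focal_gene]
  focal_snp_idx <- which.min(abs(geno$snps$pos - focal_tss))
  focal_type <- colnames(sig_true)[1]
  g <- geno$dosages[, focal_snp_idx]
  b <- mix$fractions[, focal_type]
  y <- simulate_ieqtl_expression(g, b, cfg$effect_sizes, noise_sd = ieqtl_noise_sd,
                                 intercept = log(mean(mix$bulk[focal_gene, ]) + 1),
                                 seed = cfg$seed + 3L)
  bulk <- mix$bulk
  bulk[focal_gene, ] <- exp(y)

  if (want(c("decon", "ieqtl"))) {
    paths$bulk <- write_expression_tsv(bulk, file.path(out_dir, "bulk.tsv"))
  }
  if (want("ieqtl")) {
    paths$vcf <- write_genotypes_vcf(geno, file.path(out_dir, "genotypes.vcf"))
    paths$genes <- write_gene_models_bed(genes, file.path(out_dir, "genes.bed"))
  }

  true_afc <- 1.5
  if (want(c("ase", "ieqtl"))) {
    het <- which(g == 1L)
    ase <- simulate_ase_counts(max(length(het), 1L), afc = true_afc,
                               fractions = b[het], depth = cfg$ase_depth,
                               seed = cfg$seed + 4L)
    ase$individual <- rownames(geno$dosages)[het][seq_len(nrow(ase))]
    ase$gene_id <- focal_gene
    ase$snp_id <- geno$snps$id[focal_snp_idx]
    paths$ase <- write_tsv(ase, file.path(out_dir, "ase.tsv"))
  }

  if (want(c("coloc", "ieqtl", "ldsc"))) {
    pair <- simulate_gwas_pair(gwas_scenario, cfg$n_snps, cfg$gwas_n,
                               cfg$gwas_n, seed = cfg$seed + 5L)
    # anchor the GWAS on the same synthetic chromosome coordinates
    pair$gwas$pos <- geno$snps$pos
    pair$gwas$snp <- geno$snps$id
    pair$eqtl$pos <- geno$snps$pos
    pair$eqtl$snp <- geno$snps$id
    paths$gwas <- write_tsv(pair$gwas, file.path(out_dir, "gwas.tsv"))
    paths$eqtl_summary <- write_tsv(pair$eqtl, file.path(out_dir, "eqtl_summary.tsv"))
  } else {
    pair <- NULL
  }

  truth <- list(
    fractions = mix$fractions,
    marker_sets = ref$marker_sets,
    ieqtl = list(gene = focal_gene, snp = geno$snps$id[focal_snp_idx],
                 cell_type = focal_type,
                 beta_gxb = unname(cfg$effect_sizes[["beta_gxb"]])),
    afc = true_afc,
    gwas = if (is.null(pair)) NULL else pair$truth
  )
  jsonlite::write_json(
    list(ieqtl = truth$ieqtl, afc = truth$afc,
         gwas_scenario = if (is.null(pair)) NULL else pair$truth$scenario,
         seed = cfg$seed),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  paths$truth <- file.path(out_dir, "truth.json")
  invisible(list(truth = truth, paths = paths, genes = genes,
                 genotypes = geno, bulk = bulk))
}

#' Default pipeline configuration
#'
#' All thresholds default to the study's canonical values: top-50 signature
#' genes, 1000 permutations, a +/-1 Mb cis window, interaction MAF 0.05, FDR
#' 0.05, PP4 0.5, GWAS locus threshold 1e-5 and genome-wide 5e-8, top-200
#' genes with +/-10 kb flanks for trait enrichment, Hampel k = 4.5, and the
#' ASE eligibility rule (> 10 het individuals, > 8 reads).
#'
#' @param input_dir Directory holding the study inputs (see
#'   [simulate_study()]).
#' @param output_dir Directory for stage outputs.
#' @param ... Overrides of the defaults listed above.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir, output_dir, ...) {
  cfg <- list(
    input_dir = input_dir, output_dir = output_dir,
    stages = c("signature", "deconvolve", "ieqtl", "ase", "coloc", "enrich"),
    top_n_signature = 50, n_perm = 0, window = 1e6, maf_min = 0.05,
    fdr_max = 0.05, pp4_min = 0.5, gwas_locus_p = 1e-5, gwas_sig_p = 5e-8,
    top_n_annotation = 200, flank = 10000, mad_k = 4.5, min_het = 10,
    min_reads = 8, padj_max = 0.05, lfc_min = 0.5, cell_type = NULL,
    method = "nnls", seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L) {
    stop_cellqtl("unknown config fields: ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Checks that every input file a requested stage needs exists before any
#' stage runs.
#'
#' @param config A `pipeline_config` (or YAML path readable as one).
#' @return The validated config, invisibly; errors otherwise.
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config)) {
    config <- do.call(pipeline_config, yaml::read_yaml(config))
  }
  need <- list(
    signature = file.path(config$input_dir, c("sc/matrix.mtx", "sc/cells.tsv")),
    deconvolve = file.path(config$input_dir, "bulk.tsv"),
    ieqtl = file.path(config$input_dir, c("genotypes.vcf", "genes.bed")),
    ase = file.path(config$input_dir, "ase.tsv"),
    coloc = file.path(config$input_dir, "gwas.tsv"),
    enrich = file.path(config$input_dir, "gwas.tsv")
  )
  for (st in config$stages) {
    missing <- need[[st]][!file.exists(need[[st]])]
    if (length(missing) > 0L) {
      stop_cellqtl(sprintf("stage '%s': missing input %s", st,
                           paste(missing, collapse = ", ")))
    }
  }
  invisible(config)
}

#' Run the pipeline end to end
#'
#' Executes the stages in dependency order (signature -> deconvolve -> ieqtl
#' -> ase -> coloc -> enrich) on the files in `config$input_dir`, writes TSV
#' outputs to `config$output_dir`, and returns a manifest with per-stage
#' record counts, output paths and MD5 checksums.
#'
#' @param config A `pipeline_config` (or YAML path).
#' @return The manifest (list), invisibly written to `manifest.json` as well.
#' @export
run_pipeline <- function(config) {
  config <- validate_pipeline_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)
  manifest <- list(seed = config$seed,
                   version = as.character(utils::packageVersion("cellqtl")),
                   stages = list())
  log_stage <- function(stage, files, n) {
    message(sprintf("[%s] %d records -> %s", stage, n,
                    paste(basename(files), collapse = ", ")))
    manifest$stages[[stage]] <<- list(
      n_records = n, files = as.list(files),
      md5 = as.list(unname(tools::md5sum(files))))
  }
  state <- list()

  if ("signature" %in% config$stages) {
    sc <- read_single_cell_reference(file.path(config$input_dir, "sc"))
    markers <- rank_markers(sc$counts, sc$cells$cell_type)
    tpm <- pseudo_bulk(sc$counts, sc$cells$cell_type, scale = "tpm")
    sig <- build_signature_matrix(markers, tpm, top_n = config$top_n_signature,
                                  padj_max = config$padj_max,
                                  lfc_min = config$lfc_min)
    write_tsv(markers, out("markers.tsv"))
    write_expression_tsv(unclass(sig), out("signature.tsv"))
    state$signature <- sig
    state$markers <- markers
    log_stage("signature", c(out("markers.tsv"), out("signature.tsv")), nrow(sig))
  }

  if ("deconvolve" %in% config$stages) {
    bulk <- read_expression_tsv(file.path(config$input_dir, "bulk.tsv"))
    sig <- state$signature %||% read_expression_tsv(out("signature.tsv"))
    fr <- deconvolve(bulk, sig, method = config$method, n_perm = config$n_perm,
                     seed = config$seed)
    write_tsv(fr, out("fractions.tsv"))
    state$fractions <- fr
    state$bulk <- bulk
    log_stage("deconvolve", out("fractions.tsv"), nrow(fr))
  }

  if ("ieqtl" %in% config$stages) {
    geno <- read_genotypes_vcf(file.path(config$input_dir, "genotypes.vcf"))
    genes <- read_gene_models_bed(file.path(config$input_dir, "genes.bed"))
    fr <- state$fractions %||% read_tsv(out("fractions.tsv"))
    eligible <- eligible_cell_types(fr)
    ct <- config$cell_type %||% eligible[1]
    if (!ct %in% eligible) stop_cellqtl("cell type '", ct, "' not eligible")
    b <- fraction_columns(fr)[, ct]
    res <- map_ieqtl(genes, geno, state$bulk, b, window = config$window,
                     maf_min = config$maf_min, fdr_max = config$fdr_max)
    res$top$cell_type <- ct
    write_tsv(res$top, out("ieqtl.tsv"))
    state$ieqtl <- res
    state$cell_type <- ct
    state$b <- b
    log_stage("ieqtl", out("ieqtl.tsv"), nrow(res$top))
  }

  if ("ase" %in% config$stages) {
    ase <- read_tsv(file.path(config$input_dir, "ase.tsv"))
    res <- lapply(split(ase, ase$gene_id), function(rec) {
      v <- validate_ieqtl_with_ase(rec, min_het = config$min_het,
                                   min_reads = config$min_reads,
                                   mad_k = config$mad_k)
      data.frame(gene_id = rec$gene_id[1], snp_id = rec$snp_id[1],
                 n_used = v$n_used, pearson_r = v$pearson_r,
                 p_value = v$p_value, status = v$status,
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, c(res, list(make.row.names = FALSE)))
    write_tsv(res, out("ase_validation.tsv"))
    state$ase <- res
    log_stage("ase", out("ase_validation.tsv"), nrow(res))
  }

  if ("coloc" %in% config$stages) {
    gwas <- read_tsv(file.path(config$input_dir, "gwas.tsv"))
    eqtl <- read_tsv(file.path(config$input_dir, "eqtl_summary.tsv"))
    loci <- select_gwas_loci(gwas, p_threshold = config$gwas_locus_p)
    res <- if (length(loci) == 0L) {
      data.frame(locus = character(0), pp0 = numeric(0), pp1 = numeric(0),
                 pp2 = numeric(0), pp3 = numeric(0), pp4 = numeric(0),
                 colocalized = logical(0))
    } else {
      do.call(rbind, lapply(names(loci), function(nm) {
        cc <- coloc_abf(eqtl, loci[[nm]])
        data.frame(locus = nm, pp0 = cc$pp0, pp1 = cc$pp1, pp2 = cc$pp2,
                   pp3 = cc$pp3, pp4 = cc$pp4,
                   colocalized = call_colocalized(cc, config$pp4_min),
                   stringsAsFactors = FALSE)
      }))
    }
    write_tsv(res, out("coloc.tsv"))
    state$coloc <- res
    log_stage("coloc", out("coloc.tsv"), nrow(res))
  }

  if ("enrich" %in% config$stages) {
    gwas <- read_tsv(file.path(config$input_dir, "gwas.tsv"))
    genes <- read_gene_models_bed(file.path(config$input_dir, "genes.bed"))
    markers <- state$markers %||% read_tsv(out("markers.tsv"))
    rows <- lapply(sort(unique(markers$cell_type)), function(ct) {
      ann <- build_celltype_annotation(markers, genes, cell_type = ct,
                                       top_n = config$top_n_annotation,
                                       flank = config$flank)
      cbind(cell_type = ct,
            fisher_enrichment(gwas, ann, sig_threshold = config$gwas_sig_p))
    })
    res <- adjust_enrichment(do.call(rbind, rows), config$fdr_max)
    write_tsv(res, out("enrichment.tsv"))
    log_stage("enrich", out("enrichment.tsv"), nrow(res))
  }

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
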
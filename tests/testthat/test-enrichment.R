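test_that("cell-type annotations take top-200 genes with TSS-anchored flanks", {
  mk <- data.frame(gene = sprintf("g%03d", 1:300), cell_type = "A",
                   log2_fold_change = 1, p_value = (1:300) * 1e-5,
                   adjusted_p = (1:300) * 1e-5)
  genes <- data.frame(gene_id = sprintf("g%03d", 1:300), chrom = "1",
                      tss = 20000L * (1:300))
  ann <- build_celltype_annotation(mk, genes, cell_type = "A")
  expect_equal(nrow(ann$regions), 200)
  expect_true(all(sprintf("g%03d", 1:200) %in% ann$genes))

  # flank 0: only the TSS itself is a member
  ann0 <- build_celltype_annotation(mk[1, , drop = FALSE], genes, top_n = 1,
                                    flank = 0)
  expect_true(annotate_snps(ann0, data.frame(chrom = "1", pos = 20000L)))
  expect_false(annotate_snps(ann0, data.frame(chrom = "1", pos = 20001L)))

  # two TSS 20,002 bp apart with 10 kb flanks: a SNP 10,001 bp from both is out
  g2 <- data.frame(gene_id = c("a", "b"), chrom = "1", tss = c(10000L, 30002L))
  m2 <- data.frame(gene = c("a", "b"), cell_type = "A", log2_fold_change = 1,
                   p_value = c(1e-5, 2e-5), adjusted_p = c(1e-5, 2e-5))
  ann2 <- build_celltype_annotation(m2, g2)
  expect_false(annotate_snps(ann2, data.frame(chrom = "1", pos = 20001L)))
  expect_true(annotate_snps(ann2, data.frame(chrom = "1", pos = 20000L)))
  expect_true(annotate_snps(ann2, data.frame(chrom = "1", pos = 20002L)))

  expect_warning(build_celltype_annotation(m2, g2[1, , drop = FALSE]),
                 "coordinates")
})

test_that("Fisher enrichment matches the hypergeometric tail oracle", {
  member <- rep(c(TRUE, FALSE), c(18, 82))
  sig <- rep(FALSE, 100)
  sig[c(1:8, 19:20)] <- TRUE        # a = 8, b = 2, c = 10, d = 80
  gwas <- data.frame(p = ifelse(sig, 1e-9, 0.5))
  res <- fisher_enrichment(gwas, member)
  expect_equal(res$odds_ratio, 32)
  expect_equal(res$p_value, oracle_fisher_p(8, 2, 10, 80), tolerance = 1e-9)

  # independence: equal in/out proportions give OR exactly 1
  m2 <- rep(c(TRUE, FALSE), c(40, 80))
  s2 <- c(rep(TRUE, 10), rep(FALSE, 30), rep(TRUE, 20), rep(FALSE, 60))
  res2 <- fisher_enrichment(data.frame(p = ifelse(s2, 1e-9, 0.5)), m2)
  expect_equal(res2$odds_ratio, 1)

  # zero cell: Haldane correction applied and flagged
  s3 <- c(rep(FALSE, 40), rep(TRUE, 10), rep(FALSE, 70))
  res3 <- fisher_enrichment(data.frame(p = ifelse(s3, 1e-9, 0.5)), m2)
  expect_true(res3$haldane)
  expect_equal(res3$odds_ratio, (0.5 * 70.5) / (10.5 * 40.5))

  none <- fisher_enrichment(data.frame(p = rep(0.5, 50)), rep(c(TRUE, FALSE), 25))
  expect_equal(none$p_value, 1)
  expect_true(is.na(none$odds_ratio))
})

test_that("Fisher p equals exact enumeration across random small tables", {
  withr::with_seed(17, {
    for (i in 1:20) {
      a <- sample(0:10, 1); b <- sample(0:10, 1)
      c_ <- sample(0:15, 1); d <- sample(0:15, 1)
      if (a + b == 0 || a + c_ == 0 || b + d == 0 || c_ + d == 0) next
      member <- rep(c(TRUE, FALSE, TRUE, FALSE), c(a, b, c_, d))
      sig <- rep(c(TRUE, FALSE), c(a + b, c_ + d))
      res <- fisher_enrichment(data.frame(p = ifelse(sig, 1e-9, 0.5)), member)
      expect_equal(res$p_value, oracle_fisher_p(a, b, c_, d), tolerance = 1e-9)
    }
  })
})

test_that("BH adjustment flags enriched annotation-trait pairs", {
  res <- data.frame(p_value = c(0.001, 0.01, 0.04, 0.8))
  adj <- adjust_enrichment(res)
  expect_equal(adj$fdr, p.adjust(res$p_value, "BH"))
  expect_equal(sum(adj$significant), 2)   # BH: (0.004, 0.02, 0.053, 0.8)
})

test_that("heritability partition recovers planted enrichment and the null", {
  m <- (seq_len(5000) %% 10) == 1   # 500 annotation SNPs scattered over blocks
  annot <- cbind(base = 1, ct = as.numeric(m))
  sim <- simulate_gwas_chi2(m, N = 50000, h2 = 0.5, prop_h2_annot = 0.5,
                            seed = 3)
  hp <- sldsc_enrichment(sim$chi2, 50000, annot)
  ct <- hp[hp$annotation == "ct", ]
  expect_equal(ct$prop_snps, 0.1)
  expect_gt(ct$enrichment, 4)
  expect_lt(ct$enrichment, 6)
  expect_gt(ct$coefficient_z, 3)
  expect_equal(per_variant_h2_enrichment(hp), ct$enrichment)

  # base-only annotation: enrichment is identically 1
  base_only <- sldsc_enrichment(sim$chi2, 50000,
                                cbind(base = rep(1, 5000)))
  expect_equal(base_only$enrichment, 1)

  # null: no planted enrichment
  sim0 <- simulate_gwas_chi2(m, N = 50000, h2 = 0.5, prop_h2_annot = 0.1,
                             seed = 4)
  hp0 <- sldsc_enrichment(sim0$chi2, 50000, annot)
  ct0 <- hp0[hp0$annotation == "ct", ]
  expect_lt(abs(ct0$enrichment - 1), 3 * ct0$enrichment_se)

  expect_warning(sldsc_enrichment(sim$chi2, 50000,
                                  cbind(annot, tiny = c(rep(1, 5), rep(0, 4995)))),
                 "dropping")
})

test_that("disjoint annotation partitions conserve heritability shares", {
  m <- rep(c(TRUE, FALSE), c(1000, 4000))
  annot <- cbind(base = 1, inA = as.numeric(m), outA = as.numeric(!m))
  sim <- simulate_gwas_chi2(m, N = 50000, h2 = 0.5, prop_h2_annot = 0.4,
                            seed = 5)
  hp <- sldsc_enrichment(sim$chi2, 50000, annot)
  parts <- hp[hp$annotation %in% c("inA", "outA"), ]
  expect_equal(sum(parts$prop_h2), 1, tolerance = 1e-6)
  # mixture identity: SNP-share-weighted enrichments average to 1
  expect_equal(sum(parts$prop_snps * parts$enrichment), 1, tolerance = 1e-6)
})

test_that("per-variant enrichment handles direct two-set input", {
  expect_equal(per_variant_h2_enrichment(list(h2_set = 0.1, m_set = 100,
                                              h2_total = 0.5, m_total = 500)),
               1)
  expect_equal(per_variant_h2_enrichment(list(h2_set = 0.2, m_set = 100,
                                              h2_total = 0.5, m_total = 500)),
               2)
  expect_error(per_variant_h2_enrichment(list(h2_set = 0, m_set = 0,
                                              h2_total = 1, m_total = 10)),
               "empty")
})
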
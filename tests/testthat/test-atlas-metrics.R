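test_that("QC filter applies strict exclusion bounds", {
  cells <- data.frame(
    n_genes = c(150, 200, 2064, 5001, 1000),
    n_umis = c(1000, 500, 4008, 6000, 16000),
    pct_mito = c(0.01, 0.05, 0.02, 0.01, 0.01))
  keep <- qc_filter(cells)
  # below the gene floor -> out; exact boundaries -> in; typical cell -> in;
  # above gene ceiling -> out; above UMI ceiling -> out
  expect_equal(keep, c(FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_length(qc_filter(cells[0, ]), 0)
  expect_error(qc_filter(cells, gene_bounds = c(5000, 200)), "bounds")
})

test_that("Shannon entropy matches closed-form values and its bounds", {
  expect_equal(shannon_entropy(c(A = 10, B = 10, C = 10, D = 10)), 2)
  expect_equal(shannon_entropy(c(A = 7)), 0)
  expect_equal(shannon_entropy(c(A = 3, B = 1)),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)), tolerance = 1e-7)
  expect_equal(shannon_entropy(c(A = 5, B = 0, C = 5)), 1)  # zero type drops out
  expect_error(shannon_entropy(c(A = 0, B = 0)), "nonzero")
  withr::with_seed(1, {
    for (i in 1:20) {
      k <- sample(2:8, 1)
      counts <- rpois(k, 40) + 1
      h <- shannon_entropy(counts)
      expect_gte(h, 0)
      expect_lte(h, log2(k) + 1e-12)
    }
  })
})

test_that("R_o/e enrichment matches hand-computed expectations", {
  x <- matrix(c(30, 10, 10, 30), nrow = 2, byrow = TRUE)
  r <- roe_enrichment(x)
  expect_equal(r[1, 1], 30 / (40 * 40 / 80))
  # rank-1 table: rows proportional -> all ratios 1
  p <- outer(c(2, 3, 5), c(1, 4))
  expect_equal(unname(roe_enrichment(p)), matrix(1, 3, 2), tolerance = 1e-12)
  # zero observed with positive margins -> ratio 0; zero expected -> NA
  z <- rbind(c(0, 5), c(10, 20))
  expect_equal(unname(roe_enrichment(z)[1, 1]), 0)
  zrow <- rbind(c(0, 0), c(10, 20))
  expect_true(all(is.na(roe_enrichment(zrow)[1, ])))
  expect_error(roe_enrichment(matrix(c(-1, 2, 3, 4), 2)), "nonnegative")
  # weighted mean of R over each tissue column is 1
  withr::with_seed(2, {
    tab <- matrix(rpois(12, 30) + 1, 3, 4)
    r2 <- roe_enrichment(tab)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    wm <- colSums(expected * r2) / colSums(tab)
    expect_equal(wm, rep(1, 4), tolerance = 1e-12)
  })
})

test_that("cell-cycle index is the log10 cycling ratio with flagged edges", {
  expect_equal(cell_cycle_index(100, 100), 0)
  expect_equal(cell_cycle_index(1000, 100), 1)
  expect_equal(cell_cycle_index(50, 200), log10(0.25), tolerance = 1e-7)
  expect_warning(res <- cell_cycle_index(10, 0), "noncycling")
  expect_true(is.na(res))
  expect_warning(res2 <- cell_cycle_index(0, 10), "cycling")
  expect_true(is.na(res2))
})

test_that("pseudo-bulk aggregation conserves counts and normalises correctly", {
  counts <- rbind(c(1, 2), c(3, 4), c(10, 0))
  colnames(counts) <- c("g1", "g2")
  labels <- c("A", "A", "B")
  agg <- pseudo_bulk(counts, labels)
  expect_equal(unname(agg[, "A"]), c(4, 6))
  expect_equal(sum(agg), sum(counts))
  cpm <- pseudo_bulk(counts, labels, scale = "cpm")
  expect_equal(unname(colSums(cpm)), c(1e6, 1e6), tolerance = 1e-6)
  # with per-gene lengths, TPM weights counts by 1/length before scaling
  tpm <- pseudo_bulk(counts, labels, scale = "tpm", gene_lengths = c(1000, 2000))
  expect_equal(unname(tpm[, "A"]), c(4, 3) / 7 * 1e6)
  expect_error(pseudo_bulk(counts, c("A", "B")), "per cell")
})

test_that("rank-sum marker test matches exhaustive enumeration on small groups", {
  expect_equal(cellqtl:::ranksum_pvalue(c(1, 2, 3), c(4, 5, 6)),
               oracle_ranksum_p(c(1, 2, 3), c(4, 5, 6)))
  withr::with_seed(31, {
    for (i in 1:25) {
      n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
      x <- sample(0:4, n1, replace = TRUE)   # ties likely
      y <- sample(0:4, n2, replace = TRUE)
      expect_equal(cellqtl:::ranksum_pvalue(x, y), oracle_ranksum_p(x, y))
    }
  })
  # large-sample branch agrees with the classical normal approximation
  withr::with_seed(32, {
    x <- rnorm(30); y <- rnorm(35) + 0.5
    ref <- suppressWarnings(wilcox.test(x, y, correct = TRUE,
                                        exact = FALSE)$p.value)
    expect_equal(cellqtl:::ranksum_pvalue(x, y), ref, tolerance = 1e-10)
  })
})

test_that("marker ranking finds planted markers and nothing under exchangeability", {
  ref <- make_ref(seed = 13)
  mk <- rank_markers(ref$counts, ref$cells$cell_type)
  planted <- mk[paste(mk$gene, mk$cell_type) %in%
                  unlist(lapply(names(ref$marker_sets), function(ct)
                    paste(ref$marker_sets[[ct]], ct))), ]
  expect_true(all(planted$adjusted_p < 0.05))
  expect_true(all(planted$log2_fold_change > 0.5))

  flat <- matrix(5, nrow = 20, ncol = 10,
                 dimnames = list(NULL, paste0("g", 1:10)))
  mk_null <- rank_markers(flat, rep(c("A", "B"), each = 10))
  expect_true(all(mk_null$p_value == 1))
})

test_that("signature construction keeps top-n by adjusted p with stated tie-breaks", {
  mk <- data.frame(
    gene = sprintf("g%03d", 1:60), cell_type = "A",
    log2_fold_change = 1, p_value = (1:60) * 1e-4,
    adjusted_p = (1:60) * 1e-4)
  tpm <- matrix(1, nrow = 60, ncol = 1,
                dimnames = list(sprintf("g%03d", 1:60), "A"))
  sig <- build_signature_matrix(mk, tpm, top_n = 50)
  expect_equal(nrow(sig), 50)
  expect_true(all(sprintf("g%03d", 1:50) %in% rownames(sig)))

  sig_small <- build_signature_matrix(mk[1:12, ], tpm, top_n = 50)
  expect_equal(nrow(sig_small), 12)

  tie <- mk[1:2, ]
  tie$adjusted_p <- c(0.01, 0.01)
  tie$log2_fold_change <- c(0.8, 2.5)
  sig_tie <- build_signature_matrix(tie, tpm, top_n = 1)
  expect_equal(rownames(sig_tie), "g002")   # larger |log2FC| wins the tie

  # row-order invariance
  shuffled <- mk[sample(nrow(mk)), ]
  sig_a <- build_signature_matrix(mk, tpm, top_n = 20)
  sig_b <- build_signature_matrix(shuffled, tpm, top_n = 20)
  expect_identical(rownames(sig_a), rownames(sig_b))

  none <- mk; none$adjusted_p <- 0.9
  expect_error(suppressWarnings(build_signature_matrix(none, tpm)), "passing")
})
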
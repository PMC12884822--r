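test_that("inverse normal transform maps ranks to normal quantiles", {
  out <- inverse_normal_transform(c(5, 1, 9))
  expect_equal(out[1], 0)
  expect_equal(out[2], qnorm(1 / 6), tolerance = 1e-7)
  expect_equal(out[3], qnorm(5 / 6), tolerance = 1e-7)
  x <- c(0.3, 2.5, 1.1, 7.2, 0.9)
  expect_equal(inverse_normal_transform(x), inverse_normal_transform(exp(x)))
  expect_error(inverse_normal_transform(rep(1, 5)), "distinct")
})

test_that("TMM factors are invariant to depth and match a trimmed-mean oracle", {
  y <- c(120, 85, 210, 55, 140, 95, 70, 160, 115, 60)
  same <- tmm_normalize(cbind(a = y, b = y))
  expect_equal(same$factors, c(1, 1))
  doubled <- tmm_normalize(cbind(a = y, b = 2 * y))
  expect_equal(doubled$factors, c(1, 1))
  expect_equal(unname(doubled$normalized[, 1]), unname(doubled$normalized[, 2]))

  # 10-gene toy with one 8-fold DE gene and jittered counts (no rank ties)
  obs <- c(107, 75, 1680, 53, 149, 80, 84, 160, 111, 57)
  res <- tmm_normalize(cbind(s1 = y, s2 = obs))
  expect_equal(res$factors, oracle_tmm_2sample(y, obs), tolerance = 1e-9)
  expect_error(tmm_normalize(cbind(y, rep(0, 10))), "library")
})

test_that("interaction MAF filter evaluates both enrichment halves", {
  b <- seq(0, 1, length.out = 20)
  expect_true(interaction_maf_filter(rep(1, 20), b))         # f = 0.5 everywhere
  expect_false(interaction_maf_filter(rep(0, 20), b))        # monomorphic
  # f = 0.20 overall but all carriers in the top half
  g <- c(rep(0, 10), rep(0, 2), rep(1, 8))
  expect_false(interaction_maf_filter(g, b, maf_min = 0.05))
  expect_error(interaction_maf_filter(c(0, 1, 2), c(0.1, 0.2, 0.3)), "4 samples")
})

test_that("interaction model interpolates noiseless data and matches the OLS oracle", {
  g <- c(0, 1, 2, 0, 1, 2); b <- c(0, 0, 0, 1, 1, 1)
  y <- 1 + 2 * g + 3 * b + 4 * g * b
  fit <- fit_interaction_model(y, g, b)
  expect_equal(unname(fit$beta), c(1, 2, 3, 4), tolerance = 1e-9)

  withr::with_seed(41, {
    g12 <- rbinom(12, 2, 0.4)
    b12 <- runif(12)
    y12 <- 0.5 + 0.3 * g12 + 0.7 * b12 + 0.9 * g12 * b12 + rnorm(12)
  })
  fit12 <- fit_interaction_model(y12, g12, b12)
  o <- oracle_ols(cbind(1, g12, b12, g12 * b12), y12)
  expect_equal(unname(fit12$beta), o$beta, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(unname(fit12$se), unname(o$se), tolerance = 1e-9)
  expect_equal(fit12$p_nominal, unname(o$p[4]), tolerance = 1e-9)

  expect_warning(out <- fit_interaction_model(y12, g12, b12, A = cbind(g12)),
                 "rank")
  expect_null(out)
})

test_that("interaction t-statistic is invariant to affine rescaling of b", {
  withr::with_seed(42, {
    g <- rbinom(200, 2, 0.3)
    b <- runif(200)
    y <- 0.2 * g + 0.5 * b + 0.8 * g * b + rnorm(200)
  })
  t1 <- fit_interaction_model(y, g, b)$t_gxb
  t2 <- fit_interaction_model(y, g, 2 * b + 1)$t_gxb
  expect_equal(t1, t2, tolerance = 1e-9)
})

test_that("interaction t-test is calibrated under the null", {
  rej <- vapply(1:400, function(i) {
    withr::with_seed(5000 + i, {
      g <- rbinom(150, 2, 0.3)
      b <- runif(150)
      y <- 0.5 * g + 0.5 * b + rnorm(150)
    })
    fit_interaction_model(y, g, b)$p_nominal < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("cis scan applies the closed +/-1 Mb window around the TSS", {
  gm <- simulate_genotypes(100, 3, maf_range = c(0.4, 0.5), seed = 51)
  gm$snps$pos <- c(1L, 1000001L, 1000002L)   # tss, boundary, beyond
  gene <- list(gene_id = "g1", chrom = "1", tss = 1L)
  withr::with_seed(52, {
    b <- runif(100)
    y <- rnorm(100)
  })
  rec <- cis_scan(gene, gm, y, b)
  expect_setequal(rec$snp_id, c("snp00001", "snp00002"))
  gene_off <- list(gene_id = "g2", chrom = "2", tss = 1L)
  expect_equal(nrow(cis_scan(gene_off, gm, y, b)), 0)
})

test_that("eigenMT effective test counts match known LD structures", {
  gm <- simulate_genotypes(200, 6, maf_range = c(0.3, 0.5), seed = 61)
  copies <- gm$dosages[, rep(1, 5)]
  expect_equal(eigenmt_correct(copies, 0.01)$m_eff, 1)
  expect_equal(eigenmt_correct(copies, 0.01)$p_eigenmt, 0.01)

  # three mutually orthogonal balanced columns
  orth <- cbind(rep(c(0, 2), each = 4),
                rep(c(0, 2, 0, 2), each = 2),
                rep(c(0, 2), 4))
  expect_equal(abs(cor(orth)[upper.tri(diag(3))]), rep(0, 3))
  expect_equal(eigenmt_correct(orth, 0.001)$m_eff, 3)
  expect_equal(eigenmt_correct(orth, 0.001)$p_eigenmt, 0.003)

  # two perfect-LD pairs: correlation eigenvalues (2, 2, 0, 0)
  pairs <- cbind(gm$dosages[, 1], gm$dosages[, 1],
                 gm$dosages[, 2], gm$dosages[, 2])
  expect_equal(eigenmt_correct(pairs, 0.01)$m_eff, 2)

  const <- matrix(1, nrow = 50, ncol = 3)
  expect_equal(eigenmt_correct(const, 0.2)$m_eff, 1)
  expect_gte(eigenmt_correct(gm$dosages, 0.5)$p_eigenmt, 0.5)  # never below nominal
})

test_that("ieGene calling applies BH within groups", {
  one <- data.frame(gene_id = "g1", p_eigenmt = 0.001)
  expect_equal(call_iegenes(one)$fdr, 0.001)
  expect_true(call_iegenes(one)$ie_gene)

  four <- data.frame(gene_id = paste0("g", 1:4),
                     p_eigenmt = c(0.01, 0.02, 0.03, 0.5))
  res <- call_iegenes(four)
  expect_equal(res$fdr, c(0.04, 0.04, 0.04, 0.5))
  expect_equal(sum(res$ie_gene), 3)

  all1 <- data.frame(gene_id = paste0("g", 1:5), p_eigenmt = rep(1, 5))
  expect_false(any(call_iegenes(all1)$ie_gene))
})

test_that("the full mapper recovers a planted ieQTL as the top association", {
  gm <- simulate_genotypes(300, 20, maf_range = c(0.3, 0.5), seed = 71)
  b <- withr::with_seed(72, runif(300))
  g <- gm$dosages[, 10]
  y <- simulate_ieqtl_expression(g, b, c(beta_g = 0.2, beta_b = 0.3, beta_gxb = 2),
                                 noise_sd = 0.5, seed = 73)
  genes <- data.frame(gene_id = "gene1", chrom = "1", tss = gm$snps$pos[10])
  expr <- matrix(y, nrow = 1, dimnames = list("gene1", NULL))
  res <- map_ieqtl(genes, gm, expr, b)
  expect_equal(res$top$snp_id, "snp00010")
  expect_true(res$top$ie_gene)
})
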
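# Independent brute-force oracles used across the suite. Each reimplements a
# statistic from first principles (enumeration or closed form) and must stay
# independent of the package code paths it checks.

# Two-sided Wilcoxon rank-sum p by exhaustive enumeration over all label
# assignments (subsets of the pooled sample), symmetric tail on the
# Mann-Whitney U statistic with average ranks.
oracle_ranksum_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * length(y) / 2
  subsets <- combn(length(pooled), n1)
  u_null <- apply(subsets, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(u_null - mu) >= abs(u_obs - mu) - 1e-12)
}

# Two-sided Fisher exact p by direct summation of the hypergeometric pmf over
# the whole support (all tables with the observed margins).
oracle_fisher_p <- function(a, b, c_, d) {
  m <- a + b          # significant SNPs
  n <- c_ + d         # non-significant
  k <- a + c_         # in annotation
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  sum(probs[probs <= dhyper(a, m, n, k) * (1 + 1e-7)])
}

# Coloc posteriors by exhaustive enumeration of every causal configuration:
# H0 (none), one causal SNP for trait 1 only / trait 2 only, ordered pairs of
# distinct causal SNPs, and one shared causal SNP, with per-SNP Wakefield ABFs
# and per-configuration priors p1, p2, p1*p2, p12.
oracle_coloc <- function(beta1, se1, beta2, se2, p1 = 1e-4, p2 = 1e-4,
                         p12 = 1e-5, prior_sd = 0.15) {
  abf <- function(beta, se) {
    r <- prior_sd^2 / (se^2 + prior_sd^2)
    exp(0.5 * log(1 - r) + 0.5 * r * (beta / se)^2)
  }
  a1 <- abf(beta1, se1)
  a2 <- abf(beta2, se2)
  n <- length(a1)
  s <- c(h0 = 1, h1 = 0, h2 = 0, h3 = 0, h4 = 0)
  for (i in seq_len(n)) {
    s["h1"] <- s["h1"] + p1 * a1[i]
    s["h2"] <- s["h2"] + p2 * a2[i]
    s["h4"] <- s["h4"] + p12 * a1[i] * a2[i]
    for (j in seq_len(n)) {
      if (i != j) s["h3"] <- s["h3"] + p1 * p2 * a1[i] * a2[j]
    }
  }
  unname(s / sum(s))
}

# OLS via the normal equations, with residual-variance standard errors.
oracle_ols <- function(X, y) {
  xtx_inv <- solve(t(X) %*% X)
  beta <- drop(xtx_inv %*% t(X) %*% y)
  res <- y - drop(X %*% beta)
  df <- length(y) - ncol(X)
  se <- sqrt(diag(xtx_inv) * sum(res^2) / df)
  t_stat <- beta / se
  list(beta = beta, se = se, t = t_stat, p = 2 * pt(-abs(t_stat), df))
}

# TMM scaling factors for two samples with sample 1 as reference, following
# the trimmed-mean definition directly: genes zero in either sample excluded,
# 30% two-sided trim on M, 5% on A, precision-weighted mean M, geometric-mean
# rescaling.
oracle_tmm_2sample <- function(ref, obs) {
  nO <- sum(obs); nR <- sum(ref)
  fin <- obs > 0 & ref > 0
  o <- obs[fin]; r <- ref[fin]
  M <- log2((o / nO) / (r / nR))
  A <- 0.5 * log2((o / nO) * (r / nR))
  v <- (nO - o) / (nO * o) + (nR - r) / (nR * r)
  n <- length(M)
  loL <- floor(n * 0.3) + 1; hiL <- n + 1 - loL
  loS <- floor(n * 0.05) + 1; hiS <- n + 1 - loS
  keep <- rank(M) >= loL & rank(M) <= hiL & rank(A) >= loS & rank(A) <= hiS
  f <- c(1, 2^(sum(M[keep] / v[keep]) / sum(1 / v[keep])))
  f / exp(mean(log(f)))
}

# small labelled single-cell reference reused by several files
make_ref <- function(seed = 7, n_types = 3, n_genes = 120, cells = 40) {
  cfg <- sim_config(n_cell_types = n_types, n_genes = n_genes,
                    cells_per_type = cells, seed = seed)
  simulate_single_cell_reference(cfg)
}
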
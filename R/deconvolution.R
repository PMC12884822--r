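# Standardize a bulk vector and signature over their shared genes before
# fitting: the bulk vector is z-scored, the signature is z-scored as a whole
# matrix (CIBERSORT convention), and every column plus the bulk vector is then
# mean-centred so a noiseless mixture is an exact nonnegative combination of
# the processed columns (the per-column intercepts cancel).
prepare_deconv <- function(bulk, signature) {
  S <- as.matrix(signature)
  genes <- intersect(rownames(S), names(bulk))
  if (length(genes) < 0.5 * nrow(S)) {
    stop_cellqtl("insufficient signature overlap: < 50% of signature genes in bulk")
  }
  y <- as.numeric(bulk[genes])
  if (all(y == 0)) stop_cellqtl("bulk vector is all zero over signature genes")
  S <- S[genes, , drop = FALSE]
  y <- (y - mean(y)) / sd(y)
  S <- (S - mean(S)) / sd(S)
  y <- y - mean(y)
  S <- sweep(S, 2, colMeans(S))
  list(y = y, S = S)
}

#' Estimate cell-type fractions of one bulk sample
#'
#' Solves for nonnegative mixing weights of the signature columns that best
#' reconstruct the bulk profile, then normalises them to sum to 1.
#' `method = "nnls"` minimises the least-squares residual subject to
#' nonnegativity (deterministic default). `method = "nusvr"` follows the
#' CIBERSORT scheme: linear nu-support-vector regression over
#' nu in {0.25, 0.5, 0.75}, keeping the fit with the lowest reconstruction
#' RMSE and clipping negative coefficients to zero.
#'
#' @param bulk Named numeric vector (gene -> expression) for one sample.
#' @param signature Genes x cell types `signature_matrix`.
#' @param method `"nnls"` or `"nusvr"`.
#' @return List with `fractions` (named, sums to 1), `pearson_r` and `rmse` of
#'   the reconstruction against the (standardized) bulk profile.
#' @export
deconvolve_sample <- function(bulk, signature, method = c("nnls", "nusvr")) {
  method <- match.arg(method)
  prep <- prepare_deconv(bulk, signature)
  y <- prep$y; S <- prep$S
  if (method == "nnls") {
    w <- pracma::lsqnonneg(S, y)$x
  } else {
    best <- NULL
    for (nu in c(0.25, 0.5, 0.75)) {
      fit <- e1071::svm(S, y, type = "nu-regression", kernel = "linear",
                        nu = nu, scale = FALSE)
      wk <- drop(t(fit$coefs) %*% fit$SV)
      wk[wk < 0] <- 0
      rmse_k <- sqrt(mean((drop(S %*% wk) - y)^2))
      if (is.null(best) || rmse_k < best$rmse) best <- list(w = wk, rmse = rmse_k)
    }
    w <- best$w
  }
  recon <- drop(S %*% w)
  r <- if (sd(recon) == 0) 0 else cor(recon, y)
  rmse <- sqrt(mean((recon - y)^2))
  fractions <- if (sum(w) > 0) w / sum(w) else rep(NA_real_, length(w))
  names(fractions) <- colnames(S)
  list(fractions = fractions, pearson_r = r, rmse = rmse)
}

#' Permutation significance of a deconvolution fit
#'
#' The null statistic is the reconstruction Pearson r obtained after randomly
#' permuting the gene labels of the bulk vector. The p-value uses the add-one
#' estimator `p = (1 + #\{null r >= observed r\}) / (n_perm + 1)` so it is
#' never exactly 0.
#'
#' @param bulk Named numeric bulk vector.
#' @param signature `signature_matrix`.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param method Passed to [deconvolve_sample()].
#' @return Permutation p-value in (0, 1].
#' @export
permutation_pvalue <- function(bulk, signature, n_perm = 1000, seed = 1L,
                               method = "nnls") {
  n_perm <- check_count(n_perm, "n_perm")
  obs <- deconvolve_sample(bulk, signature, method)$pearson_r
  with_rng(seed, {
    null_r <- vapply(seq_len(n_perm), function(i) {
      perm <- setNames(sample(bulk), names(bulk))
      deconvolve_sample(perm, signature, method)$pearson_r
    }, numeric(1))
    (1 + sum(null_r >= obs)) / (n_perm + 1)
  })
}

#' Deconvolve a bulk expression matrix
#'
#' Applies [deconvolve_sample()] (and optionally [permutation_pvalue()]) to
#' every column of a bulk matrix.
#'
#' @param bulk Genes x samples matrix.
#' @param signature `signature_matrix`.
#' @param method `"nnls"` or `"nusvr"`.
#' @param n_perm Permutations per sample for the significance test; 0 skips it.
#' @param seed Integer seed (used only when `n_perm > 0`).
#' @return A `cell_fraction_table`: data.frame with `sample`, one column per
#'   cell type, and fit statistics `pearson_r`, `rmse`, `permutation_p`.
#' @export
deconvolve <- function(bulk, signature, method = "nnls", n_perm = 0, seed = 1L) {
  bulk <- as.matrix(bulk)
  types <- colnames(signature)
  rows <- lapply(seq_len(ncol(bulk)), function(j) {
    fit <- deconvolve_sample(bulk[, j], signature, method)
    p <- if (n_perm > 0) {
      permutation_pvalue(bulk[, j], signature, n_perm, seed = seed + j,
                         method = method)
    } else NA_real_
    c(fit$fractions, pearson_r = fit$pearson_r, rmse = fit$rmse,
      permutation_p = p)
  })
  res <- as.data.frame(do.call(rbind, rows))
  res <- cbind(sample = colnames(bulk) %||% sprintf("sample%04d", seq_len(ncol(bulk))),
               res, stringsAsFactors = FALSE)
  class(res) <- c("cell_fraction_table", "data.frame")
  res
}

#' Cell types eligible for interaction eQTL mapping
#'
#' A cell type qualifies iff its fraction (enrichment score) is > 0 in at
#' least `min_samples` samples OR in at least `min_frac_of_samples` of all
#' samples.
#'
#' @param fractions A `cell_fraction_table` (or samples x cell types matrix /
#'   data.frame of fractions).
#' @param min_samples Absolute support threshold (default 20).
#' @param min_frac_of_samples Relative support threshold (default 0.20).
#' @return Character vector of eligible cell-type labels.
#' @export
eligible_cell_types <- function(fractions, min_samples = 20,
                                min_frac_of_samples = 0.20) {
  f <- fraction_columns(fractions)
  if (nrow(f) == 0L) stop_cellqtl("fraction table is empty")
  n_pos <- colSums(f > 0, na.rm = TRUE)
  keep <- n_pos >= min_samples | n_pos >= min_frac_of_samples * nrow(f)
  colnames(f)[keep]
}

# extract the samples x cell types numeric block from a cell_fraction_table
# (or a plain data.frame read back from its TSV form)
fraction_columns <- function(fractions) {
  if (is.data.frame(fractions) && "sample" %in% names(fractions)) {
    drop_cols <- c("sample", "pearson_r", "rmse", "permutation_p")
    m <- as.matrix(fractions[, setdiff(names(fractions), drop_cols), drop = FALSE])
    rownames(m) <- fractions$sample
    m
  } else {
    as.matrix(fractions)
  }
}
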
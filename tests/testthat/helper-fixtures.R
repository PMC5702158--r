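# Shared fixtures and independent oracles for the test suite.

tiny_config <- function(...) {
  args <- utils::modifyList(list(
    n_ref = 120, n_cohort = 60, n_genes = 4, n_tissues = 2,
    snps_per_gene = 12, n_causal_snps = 3, h2 = 0.5, prop_regulated = 1,
    snp_overlap = 1, missing_rate = 0, dose_noise_sd = 2, seed = 42
  ), list(...))
  do.call(sim_config, args)
}

# hand-buildable genotype matrix
toy_genotypes <- function(dosages, chrom = "1", pos = NULL,
                          ref = "A", alt = "G") {
  p <- ncol(dosages)
  if (is.null(pos)) pos <- seq_len(p) * 100
  genotype_matrix(
    dosages,
    tibble::tibble(id = paste0("v", seq_len(p)), chrom = chrom, pos = pos,
                   ref = rep_len(ref, p), alt = rep_len(alt, p)),
    paste0("i", seq_len(nrow(dosages)))
  )
}

# independent Benjamini-Hochberg step-up: reject H_(i) for i <= k*, where
# k* = max { k : p_(k) <= k * alpha / m }
bh_reject_oracle <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ok <- which(ps <= seq_len(m) * alpha / m)
  rejected <- rep(FALSE, m)
  if (length(ok) > 0) rejected[o[seq_len(max(ok))]] <- TRUE
  rejected
}

# brute-force all-pairs kNN distance (missing-aware normalized Euclidean)
knn_dist_oracle <- function(d, i, j) {
  shared <- !is.na(d[i, ]) & !is.na(d[j, ])
  if (!any(shared)) return(NA_real_)
  sqrt(sum((d[i, shared] - d[j, shared])^2) / sum(shared))
}

# normal-equations OLS R^2 (independent of lm.fit / QR path)
r2_oracle <- function(X, y) {
  A <- cbind(1, X)
  beta <- solve(crossprod(A), crossprod(A, y))
  res <- y - A %*% beta
  1 - sum(res^2) / sum((y - mean(y))^2)
}
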
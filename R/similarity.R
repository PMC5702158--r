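#' Between-study similarity of imputed expression
#'
#' Computes the mean imputed value of each gene-tissue pair across each
#' study's individuals and returns the Pearson correlation of those per-pair
#' means across the two studies (over shared pairs): a high correlation means
#' the two cohorts' imputations agree on which pairs are high or low.
#'
#' @param A,B [imputed_features()] matrices from two studies.
#' @return A tibble: `rho`, `p`, `n_pairs`.
#' @export
between_study_similarity <- function(A, B) {
  shared <- intersect(colnames(A$values), colnames(B$values))
  if (length(shared) < 3) stop("need at least 3 shared gene-tissue pairs")
  ma <- colMeans(A$values[, shared, drop = FALSE])
  mb <- colMeans(B$values[, shared, drop = FALSE])
  ct <- stats::cor.test(ma, mb)
  tibble::tibble(rho = unname(ct$estimate), p = ct$p.value,
                 n_pairs = length(shared))
}

#' Between-strategy similarity of imputed expression
#'
#' For two imputations of the *same* individuals (e.g. generic vs
#' cohort-specific), computes the Pearson correlation of each shared
#' gene-tissue pair across individuals and summarizes as mean and SD over
#' pairs. Pairs constant in either imputation are excluded with a message.
#'
#' @param G,C [imputed_features()] matrices sharing individuals.
#' @return A tibble: `mean_rho`, `sd_rho`, `n_pairs`, `n_excluded`.
#' @export
between_strategy_similarity <- function(G, C) {
  ind <- intersect(G$individuals, C$individuals)
  shared <- intersect(colnames(G$values), colnames(C$values))
  if (length(ind) < 3 || length(shared) < 1)
    stop("need shared individuals and at least one shared pair")
  g <- G$values[ind, shared, drop = FALSE]
  c_ <- C$values[ind, shared, drop = FALSE]
  usable <- apply(g, 2, sd) > 0 & apply(c_, 2, sd) > 0
  if (any(!usable))
    message("between_strategy_similarity: ", sum(!usable),
            " zero-variance pair(s) excluded")
  if (!any(usable)) stop("no pair with variance in both imputations")
  rho <- vapply(which(usable), function(j) cor(g[, j], c_[, j]), numeric(1))
  tibble::tibble(mean_rho = mean(rho), sd_rho = sd(rho),
                 n_pairs = sum(usable), n_excluded = sum(!usable))
}

#' Single gene-tissue feature report
#'
#' How much does one imputed feature alone say about dose? Reports the
#' Pearson correlation of the feature with observed dose, the one-feature
#' R-squared against the IWPC residuals, and add-one empirical p-values
#' against the shuffled null (and the random-signature null when the full
#' feature matrix is supplied). A constant feature yields a defined-failure
#' row (`NA` correlation) rather than an error.
#'
#' @param feature Numeric vector: one imputed gene-tissue feature.
#' @param observed_dose Observed weekly doses.
#' @param residuals IWPC residual doses.
#' @param n_perm Permutations per null; default 1000.
#' @param seed Integer seed.
#' @param all_features Optional [imputed_features()] matrix (with the feature
#'   under `feature_key`) enabling the random-signature null.
#' @param feature_key The feature's `"gene|tissue"` key within
#'   `all_features`.
#' @return A one-row tibble: `rho`, `rho_p`, `r2`, `p_shuffled`, `p_random`,
#'   `note`.
#' @export
single_feature_report <- function(feature, observed_dose, residuals,
                                  n_perm = 1000, seed = 1,
                                  all_features = NULL, feature_key = NULL) {
  if (sd(feature) == 0)
    return(tibble::tibble(rho = NA_real_, rho_p = NA_real_, r2 = NA_real_,
                          p_shuffled = NA_real_, p_random = NA_real_,
                          note = "constant feature: correlation undefined"))
  ct <- stats::cor.test(feature, observed_dose)
  X <- matrix(feature, ncol = 1)
  r2 <- regress_r2(X, residuals)
  ns <- null_shuffled(X, residuals, n_perm = n_perm,
                      seed = derive_seed(seed, "null_shuffled"))
  p_random <- NA_real_
  if (!is.null(all_features) && !is.null(feature_key)) {
    sig <- tibble::tibble(
      gene_id = sub("\\|.*$", "", feature_key),
      tissue = sub("^.*\\|", "", feature_key))
    nr <- null_random_signatures(all_features, sig, residuals,
                                 n_draws = n_perm,
                                 seed = derive_seed(seed, "null_random"))
    p_random <- empirical_p(r2, nr)
  }
  tibble::tibble(rho = unname(ct$estimate), rho_p = ct$p.value, r2 = r2,
                 p_shuffled = empirical_p(r2, ns), p_random = p_random,
                 note = NA_character_)
}
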
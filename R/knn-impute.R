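#' k-nearest-neighbour genotype imputation
#'
#' Fills missing dosages from the `k` most similar individuals. The distance
#' between two individuals is the Euclidean distance over variants non-missing
#' in both, normalized by their count (`sqrt(mean squared difference)`), so
#' individuals with different missingness patterns remain comparable. Each
#' missing entry is replaced by the unrounded mean dosage of the `k` nearest
#' individuals in whom that variant is observed; ties at the k-th neighbour
#' are broken by individual input order. Non-missing entries are untouched and
#' complete matrices pass through unchanged.
#'
#' @param G A [genotype_matrix()].
#' @param k Neighbour count; default 5.
#' @return A complete `genotype_matrix` with fractional imputed dosages.
#' @export
knn_impute <- function(G, k = 5) {
  d <- G$dosages
  if (!anyNA(d)) return(G)
  n <- nrow(d)
  if (n <= k) stop("need more than k = ", k, " individuals to impute")

  M <- !is.na(d)
  X0 <- d; X0[!M] <- 0
  X2 <- X0^2
  Mn <- M * 1
  ssd <- X2 %*% t(Mn) + Mn %*% t(X2) - 2 * X0 %*% t(X0)
  cnt <- Mn %*% t(Mn)
  dist <- sqrt(pmax(ssd, 0) / ifelse(cnt > 0, cnt, NA))
  diag(dist) <- Inf

  miss <- which(!M, arr.ind = TRUE)
  for (r in seq_len(nrow(miss))) {
    i <- miss[r, 1]; v <- miss[r, 2]
    usable <- which(M[, v] & is.finite(dist[i, ]))
    if (length(usable) < k)
      stop(sprintf("fewer than k = %d usable neighbours for individual '%s', variant '%s'",
                   k, G$individuals[i], colnames(d)[v]))
    nb <- usable[order(dist[i, usable])[seq_len(k)]]
    d[i, v] <- mean(d[nb, v])
  }
  genotype_matrix(d, G$variants, G$individuals)
}
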
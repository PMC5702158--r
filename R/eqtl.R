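#' Cis-eQTL scan of a reference panel
#'
#' For every cis-SNP x gene x tissue triple, tests the marginal association
#' of expression with dosage by simple linear regression (two-sided t-test on
#' the slope) and adjusts to q-values by Benjamini-Hochberg within each
#' tissue. Zero-variance dosages are skipped with a message.
#'
#' @param panel A `reference_panel` (see [simulate_reference_panel()]).
#' @param gene_list Optional character vector restricting the scan to these
#'   genes; default all panel genes.
#' @param window Cis window in bp (see [cis_variants()]).
#' @return A tibble of eQTL records: `gene_id`, `tissue`, `variant_id`,
#'   `slope`, `p`, `q`.
#' @export
eqtl_scan <- function(panel, gene_list = NULL, window = 1e6) {
  genes <- panel$genes
  if (!is.null(gene_list)) genes <- genes[genes$gene_id %in% gene_list, ]
  G <- panel$genotypes
  n <- length(G$individuals)
  if (n < 3) stop("need at least 3 individuals for an eQTL scan")

  per_tissue <- purrr::map(panel$tissues, function(t) {
    expr <- panel$expression[[t]]
    recs <- purrr::map_dfr(seq_len(nrow(genes)), function(gi) {
      gene <- genes[gi, ]
      cis <- cis_variants(gene, G$variants, window)
      if (nrow(cis) == 0) return(NULL)
      X <- G$dosages[, cis$id, drop = FALSE]
      y <- expr[, gene$gene_id]
      sx <- apply(X, 2, sd)
      if (any(sx == 0))
        message("eqtl_scan: ", sum(sx == 0),
                " zero-variance dosage(s) skipped for ", gene$gene_id,
                " / ", t)
      keep <- sx > 0
      if (!any(keep)) return(NULL)
      X <- X[, keep, drop = FALSE]
      r <- as.vector(cor(X, y))
      if (sd(y) == 0) r <- rep(0, ncol(X))
      r <- pmin(pmax(r, -1), 1)
      tval <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
      tval[abs(r) == 1] <- sign(r[abs(r) == 1]) * Inf
      p <- 2 * pt(-abs(tval), df = n - 2)
      slope <- unname(r * sd(y) / sx[keep])
      tibble::tibble(gene_id = gene$gene_id, tissue = t,
                     variant_id = cis$id[keep], slope = slope, p = p)
    })
    if (nrow(recs) > 0) recs$q <- p.adjust(recs$p, method = "BH")
    recs
  })
  dplyr::bind_rows(per_tissue)
}

#' Gene-tissue pairs eligible for expression imputation
#'
#' A pair is imputation-eligible when the gene has at least one significant
#' cis-eQTL in that tissue (minimum q-value at or below the threshold).
#' The boundary is inclusive: q exactly at the threshold qualifies.
#'
#' @param records eQTL record tibble from [eqtl_scan()].
#' @param threshold q-value cutoff; default 0.05.
#' @return A tibble of unique eligible `gene_id`, `tissue` pairs (with the
#'   pair's minimum q), sorted by gene then tissue.
#' @export
eligible_pairs <- function(records, threshold = 0.05) {
  if (nrow(records) == 0)
    return(tibble::tibble(gene_id = character(), tissue = character(),
                          min_q = numeric()))
  records |>
    dplyr::group_by(.data$gene_id, .data$tissue) |>
    dplyr::summarise(min_q = min(.data$q), .groups = "drop") |>
    dplyr::filter(.data$min_q <= threshold) |>
    dplyr::arrange(.data$gene_id, .data$tissue)
}
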
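#' Cis-variants of a gene
#'
#' Variants on the gene's chromosome whose position lies within `window`
#' base pairs of the gene's outer bounds. The boundary is inclusive: a SNP
#' exactly 1 Mb from a bound is cis. Input order is preserved.
#'
#' @param gene One-row data frame (or list) with `gene_id`, `chrom`,
#'   `start`, `end` (1-based inclusive).
#' @param variants Variant table with `id`, `chrom`, `pos`.
#' @param window Cis window in bp; default 1 Mb.
#' @return The subset of `variants` in cis with the gene.
#' @export
cis_variants <- function(gene, variants, window = 1e6) {
  variants <- tibble::as_tibble(variants)
  keep <- variants$chrom == gene$chrom &
    variants$pos >= gene$start - window &
    variants$pos <= gene$end + window
  variants[keep, , drop = FALSE]
}
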
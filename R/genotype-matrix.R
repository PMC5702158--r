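#' Genotype dosage matrix
#'
#' A lightweight container for genotype dosages: an individuals x variants
#' numeric matrix with values in `[0, 2]` (expected alternate-allele count;
#' fractional after imputation) or `NA` for missing, plus a variant table.
#'
#' @param dosages Numeric matrix, individuals in rows, variants in columns.
#' @param variants Data frame with columns `id`, `chrom`, `pos`, `ref`, `alt`
#'   (1-based positions), one row per column of `dosages`.
#' @param individuals Character vector of individual IDs; defaults to the
#'   row names of `dosages`.
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(dosages, variants, individuals = rownames(dosages)) {
  variants <- tibble::as_tibble(variants)
  stopifnot(ncol(dosages) == nrow(variants))
  if (is.null(individuals)) individuals <- paste0("ind", seq_len(nrow(dosages)))
  individuals <- as.character(individuals)
  if (anyDuplicated(individuals)) stop("duplicate individual IDs")
  if (anyDuplicated(variants$id)) stop("duplicate variant IDs")
  if (any(variants$pos < 1)) stop("positions must be >= 1 (1-based)")
  if (any(variants$ref == variants$alt)) stop("ref and alt alleles must differ")
  if (!all(is.na(dosages))) {
    rng <- range(dosages, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 2)
      stop("dosages must lie in [0, 2] or be NA")
  }
  dosages <- as.matrix(dosages)
  dimnames(dosages) <- list(individuals, variants$id)
  structure(list(dosages = dosages, variants = variants,
                 individuals = individuals),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d variants (%.2f%% missing)\n",
              length(x$individuals), nrow(x$variants),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Tidy a genotype matrix into long format
#'
#' @param x A [genotype_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `individual`, `variant_id`, `dosage`.
#' @export
tidy.genotype_matrix <- function(x, ...) {
  tibble::tibble(
    individual = rep(x$individuals, times = ncol(x$dosages)),
    variant_id = rep(colnames(x$dosages), each = nrow(x$dosages)),
    dosage = as.vector(x$dosages)
  )
}

#' Subset a genotype matrix to a set of variant IDs
#'
#' @param G A [genotype_matrix()].
#' @param variant_ids Character vector of variant IDs to keep (order kept).
#' @return A `genotype_matrix` restricted to those variants.
#' @export
subset_variants <- function(G, variant_ids) {
  keep <- match(variant_ids, G$variants$id)
  if (anyNA(keep)) stop("unknown variant IDs: ",
                        paste(head(variant_ids[is.na(keep)], 3), collapse = ", "))
  genotype_matrix(G$dosages[, keep, drop = FALSE], G$variants[keep, ],
                  G$individuals)
}

#' Imputed gene-tissue feature matrix
#'
#' Container for imputed (genetically regulated) expression: an
#' individuals x features numeric matrix whose columns are gene-tissue pairs.
#'
#' @param values Numeric matrix, individuals in rows.
#' @param features Data frame with columns `gene_id`, `tissue`, one row per
#'   column of `values`.
#' @param individuals Character IDs; default row names of `values`.
#' @return An `imputed_features` object.
#' @export
imputed_features <- function(values, features, individuals = rownames(values)) {
  features <- tibble::as_tibble(features)
  stopifnot(ncol(values) == nrow(features))
  if (is.null(individuals)) individuals <- paste0("ind", seq_len(nrow(values)))
  key <- paste(features$gene_id, features$tissue, sep = "|")
  if (anyDuplicated(key)) stop("duplicate gene-tissue pairs")
  if (any(!is.finite(values))) stop("feature values must be finite")
  values <- as.matrix(values)
  dimnames(values) <- list(as.character(individuals), key)
  structure(list(values = values, features = features,
                 individuals = as.character(individuals)),
            class = "imputed_features")
}

#' @export
print.imputed_features <- function(x, ...) {
  cat(sprintf("<imputed_features> %d individuals x %d gene-tissue pairs\n",
              length(x$individuals), nrow(x$features)))
  invisible(x)
}

#' @export
dim.imputed_features <- function(x) dim(x$values)

#' Tidy an imputed feature matrix into long format
#'
#' @param x An [imputed_features()] object.
#' @param ... Unused.
#' @return A tibble with columns `individual`, `gene_id`, `tissue`, `value`.
#' @export
tidy.imputed_features <- function(x, ...) {
  n <- nrow(x$values)
  tibble::tibble(
    individual = rep(x$individuals, times = ncol(x$values)),
    gene_id = rep(x$features$gene_id, each = n),
    tissue = rep(x$features$tissue, each = n),
    value = as.vector(x$values)
  )
}

#' Canonical key of a gene-tissue pair
#'
#' @param gene_id,tissue Character vectors.
#' @return `"gene|tissue"` strings.
#' @export
feature_key <- function(gene_id, tissue) paste(gene_id, tissue, sep = "|")
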
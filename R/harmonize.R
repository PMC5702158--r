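#' Harmonize cohort variants against a reference panel
#'
#' Matches variants by `(chrom, pos)`. An exact `ref`/`alt` match maps
#' directly; swapped alleles map with the dosage transform `d -> 2 - d` and
#' are recorded as flipped; strand-ambiguous swaps (A/T or C/G pairs, where a
#' swap is indistinguishable from a strand flip) and allele mismatches are
#' excluded. Genotype platforms differ in which strand and allele order they
#' report, so this step is required before any cross-platform model transfer.
#'
#' @param cohort,reference [genotype_matrix()] objects.
#' @return A list: `mapping` (tibble `cohort_id`, `reference_id`, `flipped`),
#'   `flipped` (cohort variant IDs needing `2 - d`), `excluded` (tibble
#'   `cohort_id`, `reason`).
#' @export
harmonize <- function(cohort, reference) {
  cv <- cohort$variants
  rv <- reference$variants
  key_c <- paste(cv$chrom, cv$pos)
  key_r <- paste(rv$chrom, rv$pos)
  m <- match(key_c, key_r)

  mapping <- list(); excluded <- list()
  for (i in seq_along(m)) {
    j <- m[i]
    if (is.na(j)) {
      excluded[[length(excluded) + 1L]] <-
        tibble::tibble(cohort_id = cv$id[i], reason = "no positional match")
      next
    }
    direct <- cv$ref[i] == rv$ref[j] && cv$alt[i] == rv$alt[j]
    swapped <- cv$ref[i] == rv$alt[j] && cv$alt[i] == rv$ref[j]
    ambiguous <- paste0(cv$ref[i], cv$alt[i]) %in% c("AT", "TA", "CG", "GC")
    if (direct) {
      mapping[[length(mapping) + 1L]] <-
        tibble::tibble(cohort_id = cv$id[i], reference_id = rv$id[j],
                       flipped = FALSE)
    } else if (swapped && !ambiguous) {
      mapping[[length(mapping) + 1L]] <-
        tibble::tibble(cohort_id = cv$id[i], reference_id = rv$id[j],
                       flipped = TRUE)
    } else {
      reason <- if (swapped) "strand-ambiguous swap" else "allele mismatch"
      excluded[[length(excluded) + 1L]] <-
        tibble::tibble(cohort_id = cv$id[i], reason = reason)
    }
  }
  mapping <- if (length(mapping)) dplyr::bind_rows(mapping) else
    tibble::tibble(cohort_id = character(), reference_id = character(),
                   flipped = logical())
  excluded <- if (length(excluded)) dplyr::bind_rows(excluded) else
    tibble::tibble(cohort_id = character(), reason = character())
  if (nrow(mapping) == 0)
    message("harmonize: no variants could be matched")
  if (nrow(excluded) > 0)
    message("harmonize: ", nrow(excluded), " variant(s) excluded")
  list(mapping = mapping, flipped = mapping$cohort_id[mapping$flipped],
       excluded = excluded)
}

#' Apply a harmonization mapping to cohort dosages
#'
#' Returns the cohort genotypes on the reference's variant IDs and allele
#' orientation: mapped variants only, flipped variants transformed
#' `d -> 2 - d`.
#'
#' @param cohort A [genotype_matrix()].
#' @param harmonization Result of [harmonize()].
#' @return A `genotype_matrix` whose variant IDs are reference IDs.
#' @export
apply_harmonization <- function(cohort, harmonization) {
  map <- harmonization$mapping
  if (nrow(map) == 0) stop("empty harmonization mapping")
  idx <- match(map$cohort_id, cohort$variants$id)
  d <- cohort$dosages[, idx, drop = FALSE]
  d[, map$flipped] <- 2 - d[, map$flipped, drop = FALSE]
  v <- cohort$variants[idx, ]
  v$id <- map$reference_id
  # flipped variants: report reference allele orientation
  flip <- map$flipped
  tmp <- v$ref[flip]; v$ref[flip] <- v$alt[flip]; v$alt[flip] <- tmp
  genotype_matrix(d, v, cohort$individuals)
}

#' Cross-platform genotype concordance
#'
#' Fraction of (shared individual, shared variant) cells where the two
#' matrices disagree; a missing call on either side counts as a mismatch.
#' Shared variants are matched by ID (harmonize first if platforms differ).
#'
#' @param A,B [genotype_matrix()] objects.
#' @param shared_individuals Optional character vector; default is the
#'   intersection of the two individual sets.
#' @return The mismatch fraction in `[0, 1]`.
#' @export
concordance <- function(A, B, shared_individuals = NULL) {
  ind <- shared_individuals %||% intersect(A$individuals, B$individuals)
  vars <- intersect(A$variants$id, B$variants$id)
  if (length(ind) == 0 || length(vars) == 0)
    stop("no shared individuals/variants to compare")
  a <- A$dosages[ind, vars, drop = FALSE]
  b <- B$dosages[ind, vars, drop = FALSE]
  mism <- is.na(a) | is.na(b) | (a != b)
  mism[is.na(mism)] <- TRUE
  mean(mism)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
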
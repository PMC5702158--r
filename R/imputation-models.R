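#' Train a sparse cis-SNP expression-imputation model
#'
#' Fits the genetically regulated component of a gene's expression in one
#' tissue as an L1-penalized linear function of cis-SNP dosages on the
#' reference panel, with fivefold cross-validation over the fixed penalty
#' grid ([cv_lasso()]). Under the cohort-specific strategy, predictors are
#' restricted to the SNPs the target cohort actually measured
#' (`cohort_snps`), so the model is transferable without any dosage
#' substitution.
#'
#' @param panel A `reference_panel`.
#' @param gene_id,tissue The gene-tissue pair (should be eQTL-eligible,
#'   see [eligible_pairs()]).
#' @param cohort_snps Optional character vector of reference variant IDs
#'   measured in the target cohort; `NULL` uses all cis-SNPs (the generic
#'   training setting).
#' @param folds CV folds; default 5.
#' @param seed Fold-assignment seed.
#' @param window Cis window in bp.
#' @return An `imputation_model`: gene/tissue, intercept, `weights` tibble
#'   (nonzero only, with alleles and reference mean dosage), `strategy`,
#'   selected `lambda`, `cv_mse`.
#' @export
train_imputation_model <- function(panel, gene_id, tissue, cohort_snps = NULL,
                                   folds = 5, seed = 1, window = 1e6) {
  gene <- panel$genes[panel$genes$gene_id == gene_id, ]
  if (nrow(gene) != 1) stop("unknown gene: ", gene_id)
  if (!tissue %in% panel$tissues) stop("unknown tissue: ", tissue)
  cis <- cis_variants(gene, panel$genotypes$variants, window)
  strategy <- if (is.null(cohort_snps)) "generic" else "cohort_specific"
  if (!is.null(cohort_snps)) cis <- cis[cis$id %in% cohort_snps, ]
  if (nrow(cis) == 0)
    stop("empty predictor set for ", gene_id, " / ", tissue,
         " (no usable cis-SNP)")
  X <- panel$genotypes$dosages[, cis$id, drop = FALSE]
  if (anyNA(X)) stop("reference genotypes must be complete")
  y <- panel$expression[[tissue]][, gene_id]

  fit <- cv_lasso(X, y, folds = folds, seed = seed)
  nz <- fit$weights != 0
  weights <- dplyr::mutate(cis[nz, c("id", "chrom", "pos", "ref", "alt")],
                           weight = unname(fit$weights[nz]),
                           ref_mean = colMeans(X)[nz])
  names(weights)[1] <- "variant_id"
  structure(list(gene_id = gene_id, tissue = tissue,
                 intercept = fit$intercept, weights = weights,
                 strategy = strategy, lambda = fit$lambda,
                 cv_mse = fit$cv_mse),
            class = "imputation_model")
}

#' @export
print.imputation_model <- function(x, ...) {
  cat(sprintf("<imputation_model> %s / %s (%s): %d SNP(s), lambda = %.4g, CV MSE = %.4g\n",
              x$gene_id, x$tissue, x$strategy, nrow(x$weights), x$lambda,
              x$cv_mse))
  invisible(x)
}

#' @export
tidy.imputation_model <- function(x, ...) {
  dplyr::mutate(x$weights, gene_id = x$gene_id, tissue = x$tissue,
                .before = 1)
}

#' @export
glance.imputation_model <- function(x, ...) {
  tibble::tibble(gene_id = x$gene_id, tissue = x$tissue,
                 strategy = x$strategy, n_snps = nrow(x$weights),
                 intercept = x$intercept, lambda = x$lambda,
                 cv_mse = x$cv_mse)
}

#' Train imputation models for a set of eligible gene-tissue pairs
#'
#' @param panel A `reference_panel`.
#' @param pairs Tibble with `gene_id`, `tissue` (e.g. from
#'   [eligible_pairs()]).
#' @inheritParams train_imputation_model
#' @return A `weights_db`: list of `imputation_model`s keyed
#'   `"gene|tissue"`, sorted.
#' @export
train_imputation_models <- function(panel, pairs, cohort_snps = NULL,
                                    folds = 5, seed = 1, window = 1e6) {
  pairs <- dplyr::arrange(tibble::as_tibble(pairs), .data$gene_id, .data$tissue)
  models <- purrr::map(seq_len(nrow(pairs)), function(i) {
    tryCatch(
      train_imputation_model(panel, pairs$gene_id[i], pairs$tissue[i],
                             cohort_snps = cohort_snps, folds = folds,
                             seed = derive_seed(seed, "cv_folds", i),
                             window = window),
      error = function(e) {
        message("skipping ", pairs$gene_id[i], " / ", pairs$tissue[i], ": ",
                conditionMessage(e))
        NULL
      })
  })
  models <- purrr::compact(models)
  names(models) <- purrr::map_chr(models, ~ feature_key(.x$gene_id, .x$tissue))
  structure(models[order(names(models))], class = "weights_db")
}

#' @export
print.weights_db <- function(x, ...) {
  cat(sprintf("<weights_db> %d gene-tissue model(s)\n", length(x)))
  invisible(x)
}

#' Impute gene-tissue expression for a cohort
#'
#' Applies trained (or loaded) imputation models to a cohort's dosage matrix:
#' `value = intercept + sum(weight x dosage)`. Cohort-specific models must
#' find every model SNP in the (complete, kNN-imputed) cohort matrix and
#' error otherwise — their contract is that they were trained on the cohort's
#' platform. Generic models substitute the reference-panel mean dosage for a
#' model SNP the cohort did not measure, which after centering is equivalent
#' to dropping the term.
#'
#' @param models A `weights_db` or list of `imputation_model`s.
#' @param G Cohort [genotype_matrix()] on reference variant IDs (harmonized;
#'   complete for cohort-specific models).
#' @param reference_means Optional named per-variant mean dosages overriding
#'   the means stored in each model.
#' @return An [imputed_features()] matrix, columns sorted by gene then tissue.
#' @export
impute_expression <- function(models, G, reference_means = NULL) {
  if (inherits(models, "imputation_model")) models <- list(models)
  models <- unname(as.list(models))
  keys <- purrr::map_chr(models, ~ feature_key(.x$gene_id, .x$tissue))
  ord <- order(keys)
  models <- models[ord]; keys <- keys[ord]
  n <- length(G$individuals)
  vals <- matrix(NA_real_, n, length(models))
  for (m in seq_along(models)) {
    mod <- models[[m]]
    w <- mod$weights
    measured <- w$variant_id %in% G$variants$id
    if (mod$strategy == "cohort_specific" && any(!measured))
      stop("cohort-specific model ", keys[m], " references unmeasured SNP(s): ",
           paste(head(w$variant_id[!measured], 3), collapse = ", "))
    v <- rep(mod$intercept, n)
    if (any(measured)) {
      D <- G$dosages[, w$variant_id[measured], drop = FALSE]
      if (anyNA(D))
        stop("missing dosages for model ", keys[m],
             "; run knn_impute() first")
      v <- v + as.vector(D %*% w$weight[measured])
    }
    if (any(!measured)) {
      means <- if (!is.null(reference_means))
        reference_means[w$variant_id[!measured]] else w$ref_mean[!measured]
      if (anyNA(means))
        stop("no reference mean dosage for unmeasured SNP(s) of ", keys[m])
      v <- v + sum(w$weight[!measured] * means)
    }
    vals[, m] <- v
  }
  feats <- tibble::tibble(
    gene_id = purrr::map_chr(models, "gene_id"),
    tissue = purrr::map_chr(models, "tissue")
  )
  imputed_features(vals, feats, G$individuals)
}

weights_db_cols <- c("gene_id", "tissue", "variant_id", "chrom", "pos",
                     "ref", "alt", "weight", "ref_mean")

#' Save / load a weights database
#'
#' File-backed collection of imputation models (the generic strategy's
#' pre-trained weights). TSV schema: `gene_id`, `tissue`, `variant_id`,
#' `chrom`, `pos`, `ref`, `alt`, `weight`, `ref_mean`; each model's intercept
#' is a row with `variant_id = "__intercept__"`.
#'
#' @param db A `weights_db` (or list of `imputation_model`s).
#' @param path TSV path.
#' @return `save_weights_db()` returns `path` invisibly; `load_weights_db()`
#'   returns a `weights_db` whose models carry `strategy = "generic"`.
#' @export
save_weights_db <- function(db, path) {
  rows <- purrr::map_dfr(unname(as.list(db)), function(m) {
    dplyr::bind_rows(
      tibble::tibble(gene_id = m$gene_id, tissue = m$tissue,
                     variant_id = "__intercept__", chrom = NA_character_,
                     pos = NA_integer_, ref = NA_character_,
                     alt = NA_character_, weight = m$intercept,
                     ref_mean = NA_real_),
      dplyr::mutate(m$weights, gene_id = m$gene_id, tissue = m$tissue,
                    .before = 1))
  })
  readr::write_tsv(rows[, weights_db_cols], path, na = "")
  invisible(path)
}

#' @rdname save_weights_db
#' @export
load_weights_db <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           chrom = readr::col_character(),
                           ref = readr::col_character(),
                           alt = readr::col_character()))
  unknown <- setdiff(names(tab), weights_db_cols)
  if (length(unknown))
    stop("unknown column(s) in weights DB: ", paste(unknown, collapse = ", "))
  miss <- setdiff(weights_db_cols, names(tab))
  if (length(miss))
    stop("weights DB missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(tab) == 0) {
    warning("empty weights database")
    return(structure(list(), class = "weights_db"))
  }
  if (anyDuplicated(tab[, c("gene_id", "tissue", "variant_id")]))
    stop("duplicate (gene, tissue, variant) rows in weights DB")
  models <- tab |>
    dplyr::group_by(.data$gene_id, .data$tissue) |>
    dplyr::group_map(function(g, key) {
      ic <- g$variant_id == "__intercept__"
      if (sum(ic) != 1)
        stop("model ", key$gene_id, "/", key$tissue,
             " must have exactly one intercept row")
      structure(list(
        gene_id = key$gene_id, tissue = key$tissue,
        intercept = g$weight[ic],
        weights = g[!ic, c("variant_id", "chrom", "pos", "ref", "alt",
                           "weight", "ref_mean")],
        strategy = "generic", lambda = NA_real_, cv_mse = NA_real_
      ), class = "imputation_model")
    })
  names(models) <- purrr::map_chr(models, ~ feature_key(.x$gene_id, .x$tissue))
  structure(models[order(names(models))], class = "weights_db")
}
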
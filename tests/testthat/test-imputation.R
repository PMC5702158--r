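# one trained panel shared across this file
imp_sim <- simulate_reference_panel(tiny_config(n_ref = 200, seed = 33))
imp_eligible <- eligible_pairs(eqtl_scan(imp_sim$panel))

toy_model <- function(weights_tbl, intercept = 0,
                      strategy = "cohort_specific") {
  structure(list(gene_id = "G1", tissue = "t1", intercept = intercept,
                 weights = weights_tbl, strategy = strategy,
                 lambda = 0.1, cv_mse = 0.1),
            class = "imputation_model")
}

wtbl <- function(ids, w, ref_mean = 1, pos = NULL) {
  tibble::tibble(variant_id = ids, chrom = "1",
                 pos = pos %||% seq_along(ids) * 100,
                 ref = "A", alt = "G", weight = w,
                 ref_mean = rep_len(ref_mean, length(ids)))
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("imputation is intercept + weighted dosage sum", {
  G <- toy_genotypes(matrix(c(2, 0), 2, 1))
  m <- toy_model(wtbl("v1", 1.0))
  expect_equal(unname(impute_expression(m, G)$values[, 1]), c(2, 0))
  m2 <- toy_model(wtbl(character(), numeric()), intercept = 3.5)
  expect_equal(unname(impute_expression(m2, G)$values[, 1]), c(3.5, 3.5))
})

test_that("generic models substitute the reference mean for unmeasured SNPs", {
  G <- toy_genotypes(matrix(c(2, 0), 2, 1))
  m <- toy_model(wtbl(c("v1", "unmeasured"), c(1, 1), ref_mean = c(1, 0.6),
                      pos = c(100, 900)),
                 strategy = "generic")
  vals <- impute_expression(m, G)$values[, 1]
  expect_equal(unname(vals), c(2, 0) + 0.6)
  # cohort-specific contract: unmeasured SNP is an error
  mc <- toy_model(wtbl(c("v1", "unmeasured"), c(1, 1), pos = c(100, 900)))
  expect_error(impute_expression(mc, G), "unmeasured")
})

test_that("cohort-specific training keeps its support inside the cohort SNPs", {
  pair <- imp_eligible[1, ]
  cis <- imp_sim$truth$variants$id[imp_sim$truth$variants$gene_id ==
                                     pair$gene_id]
  cohort_snps <- cis[seq(1, length(cis), by = 2)]
  m <- train_imputation_model(imp_sim$panel, pair$gene_id, pair$tissue,
                              cohort_snps = cohort_snps, seed = 3)
  expect_true(all(m$weights$variant_id %in% cohort_snps))
  expect_equal(m$strategy, "cohort_specific")
  full <- train_imputation_model(imp_sim$panel, pair$gene_id, pair$tissue,
                                 seed = 3)
  expect_gte(m$cv_mse, full$cv_mse - 1e-10)
})

test_that("empty predictor sets raise a distinct error", {
  pair <- imp_eligible[1, ]
  expect_error(
    train_imputation_model(imp_sim$panel, pair$gene_id, pair$tissue,
                           cohort_snps = "no_such_snp", seed = 1),
    "empty predictor set")
  expect_error(train_imputation_model(imp_sim$panel, "nope", "tissue01"),
               "unknown gene")
})

test_that("weights database round-trips and validates its schema", {
  db <- train_imputation_models(imp_sim$panel, imp_eligible[1:3, ], seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  save_weights_db(db, path)
  back <- load_weights_db(path)
  expect_equal(length(back), length(db))
  for (k in names(db)) {
    expect_equal(back[[k]]$intercept, db[[k]]$intercept)
    expect_equal(back[[k]]$weights$variant_id, db[[k]]$weights$variant_id)
    expect_equal(back[[k]]$weights$weight, db[[k]]$weights$weight)
    expect_equal(back[[k]]$strategy, "generic")
  }

  tab <- readr::read_tsv(path, show_col_types = FALSE)
  dup <- dplyr::bind_rows(tab, tab[2, ])
  readr::write_tsv(dup, path)
  expect_error(load_weights_db(path), "duplicate")
  bad <- dplyr::mutate(tab, surprise = 1)
  readr::write_tsv(bad, path)
  expect_error(load_weights_db(path), "unknown column")
  readr::write_tsv(tab[0, ], path)
  expect_warning(empty <- load_weights_db(path), "empty")
  expect_length(empty, 0)
})

test_that("generic and cohort-specific agree when SNP sets coincide", {
  all_snps <- imp_sim$panel$genotypes$variants$id
  pairs <- imp_eligible[1:2, ]
  db_g <- train_imputation_models(imp_sim$panel, pairs, seed = 7)
  db_c <- train_imputation_models(imp_sim$panel, pairs,
                                  cohort_snps = all_snps, seed = 7)
  cfg <- tiny_config(n_ref = 200, seed = 33)
  ch <- simulate_cohort(cfg, imp_sim$truth)
  fg <- impute_expression(db_g, ch$genotypes)
  fc <- impute_expression(db_c, ch$genotypes)
  expect_equal(fg$values, fc$values)
})

test_that("imputed feature count matches eligible pairs with usable SNPs", {
  db <- train_imputation_models(imp_sim$panel, imp_eligible, seed = 9)
  cfg <- tiny_config(n_ref = 200, seed = 33)
  ch <- simulate_cohort(cfg, imp_sim$truth)
  fx <- impute_expression(db, ch$genotypes)
  expect_equal(ncol(fx$values), nrow(imp_eligible))
  expect_equal(colnames(fx$values),
               sort(paste(imp_eligible$gene_id, imp_eligible$tissue,
                          sep = "|")))
  expect_true(all(is.finite(fx$values)))
})

test_that("held-out imputation tracks the true genetic value at h2 = 0.5", {
  db <- train_imputation_models(imp_sim$panel, imp_eligible, seed = 11)
  cfg <- tiny_config(n_ref = 200, seed = 33)
  ch <- simulate_cohort(cfg, imp_sim$truth, cohort_index = 2)
  fx <- impute_expression(db, ch$genotypes)
  keys <- intersect(colnames(fx$values), colnames(ch$genetic_values))
  cors <- vapply(keys, function(k) cor(fx$values[, k],
                                       ch$genetic_values[, k]), numeric(1))
  expect_gte(median(cors), 0.7)
})
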
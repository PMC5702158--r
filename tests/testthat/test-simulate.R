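test_that("config validation rejects out-of-range parameters", {
  expect_error(tiny_config(h2 = 1.2), "h2")
  expect_error(tiny_config(h2 = -0.1), "h2")
  expect_error(tiny_config(n_causal_snps = 20, snps_per_gene = 10),
               "n_causal_snps")
  expect_error(tiny_config(maf_range = c(0.5, 0.1)), "maf_range")
  expect_error(tiny_config(snp_overlap = 1.5), "snp_overlap")
  expect_error(sim_config(dose_low = 50, dose_high = 49), "low < high")
})

test_that("config YAML round-trips including planted signature", {
  cfg <- tiny_config(signature_pairs = data.frame(
    gene_id = "G001", tissue = "tissue01", effect = 2.5))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(unclass(back), unclass(cfg))
})

test_that("h2 = 1 makes expression equal its genetic value exactly", {
  sim <- simulate_reference_panel(tiny_config(h2 = 1, seed = 3))
  reg <- sim$truth$regulated
  for (i in which(reg$regulated)) {
    expr <- sim$panel$expression[[reg$tissue[i]]][, reg$gene_id[i]]
    expect_equal(expr, unname(sim$truth$genetic_ref[, i]),
                 ignore_attr = TRUE)
  }
})

test_that("h2 = 0 leaves expression independent of genotype", {
  sim <- simulate_reference_panel(tiny_config(h2 = 0, n_ref = 400, seed = 5))
  expect_equal(nrow(sim$truth$weights), 0)
  g <- sim$panel$genes$gene_id[1]
  expr <- sim$panel$expression[[1]][, g]
  snps <- sim$truth$variants$id[sim$truth$variants$gene_id == g]
  cors <- abs(cor(sim$panel$genotypes$dosages[, snps], expr))
  expect_lt(max(cors), 0.2)  # Monte-Carlo bound at n = 400
})

test_that("panels are bit-identical under the same seed and hit the target h2", {
  cfg <- tiny_config(n_ref = 300, snps_per_gene = 50, n_causal_snps = 5,
                     h2 = 0.5, n_genes = 6, seed = 7)
  a <- simulate_reference_panel(cfg)
  b <- simulate_reference_panel(cfg)
  expect_identical(a$panel$genotypes$dosages, b$panel$genotypes$dosages)
  expect_identical(a$panel$expression, b$panel$expression)
  expect_identical(a$truth$weights, b$truth$weights)

  reg <- a$truth$regulated
  ratios <- vapply(which(reg$regulated), function(i) {
    expr <- a$panel$expression[[reg$tissue[i]]][, reg$gene_id[i]]
    var(a$truth$genetic_ref[, i]) / var(expr)
  }, numeric(1))
  expect_true(all(abs(ratios - 0.5) < 0.1))
})

test_that("dosages stay in [0, 2], expression finite, MAFs near target", {
  cfg <- tiny_config(n_ref = 400, maf_range = c(0.1, 0.4), seed = 8)
  sim <- simulate_reference_panel(cfg)
  d <- sim$panel$genotypes$dosages
  expect_true(all(d >= 0 & d <= 2))
  expect_true(all(vapply(sim$panel$expression,
                         function(m) all(is.finite(m)), logical(1))))
  emp <- colMeans(d) / 2
  expect_true(all(abs(emp - sim$truth$variants$maf) < 0.12))
})

test_that("cohort SNP set equals reference set at full overlap", {
  cfg <- tiny_config(snp_overlap = 1, seed = 2)
  sim <- simulate_reference_panel(cfg)
  ch <- simulate_cohort(cfg, sim$truth)
  expect_setequal(ch$genotypes$variants$id, sim$panel$genotypes$variants$id)
})

test_that("noiseless dose with no signature equals the IWPC prediction", {
  cfg <- tiny_config(dose_noise_sd = 0, seed = 6)
  sim <- simulate_reference_panel(cfg)
  ch <- simulate_cohort(cfg, sim$truth)
  expect_equal(ch$doses$observed_dose, ch$doses$predicted_dose)
  expect_equal(ch$doses$residual, rep(0, nrow(ch$doses)))
})

test_that("noiseless planted signature yields R^2 = 1 on true expression", {
  cfg <- tiny_config(dose_noise_sd = 0, seed = 9, signature_pairs =
    data.frame(gene_id = c("G001", "G002"), tissue = "tissue01",
               effect = c(4, -3)))
  sim <- simulate_reference_panel(cfg)
  ch <- simulate_cohort(cfg, sim$truth)
  keys <- c("G001|tissue01", "G002|tissue01")
  r2 <- regress_r2(ch$genetic_values[, keys], ch$doses$residual)
  expect_equal(r2, 1, tolerance = 1e-10)
})

test_that("dichotomization keeps 35 and 49.5 but drops (35, 49]", {
  keep <- dichotomize_keep(c(30, 35, 40, 49, 49.5))
  expect_identical(keep, c(TRUE, TRUE, FALSE, FALSE, TRUE))
  cfg <- tiny_config(dichotomize = TRUE, dose_noise_sd = 15, seed = 10,
                     n_cohort = 200)
  sim <- simulate_reference_panel(cfg)
  ch <- simulate_cohort(cfg, sim$truth)
  expect_true(all(ch$doses$observed_dose <= 35 | ch$doses$observed_dose > 49))
  expect_lt(nrow(ch$doses), 200)
})

test_that("snp_overlap = 0 with a planted signature is rejected", {
  cfg <- tiny_config(snp_overlap = 0, signature_pairs = data.frame(
    gene_id = "G001", tissue = "tissue01", effect = 1))
  sim_cfg <- tiny_config(seed = cfg$seed)
  sim <- simulate_reference_panel(sim_cfg)
  expect_error(simulate_cohort(cfg, sim$truth), "no imputable")
})

test_that("plant_missingness: identity, saturation and binomial rate", {
  G <- toy_genotypes(matrix(rbinom(100 * 100, 2, 0.3), 100, 100))
  expect_identical(plant_missingness(G, 0, seed = 1)$dosages, G$dosages)
  expect_true(all(is.na(plant_missingness(G, 1, seed = 1)$dosages)))
  Gm <- plant_missingness(G, 0.011, seed = 4)
  n_miss <- sum(is.na(Gm$dosages))
  sd3 <- 3 * sqrt(10000 * 0.011 * 0.989)
  expect_gt(n_miss, 110 - sd3)
  expect_lt(n_miss, 110 + sd3)
  # determinism
  expect_identical(plant_missingness(G, 0.011, seed = 4)$dosages, Gm$dosages)
})
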
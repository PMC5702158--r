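#' Simulate a reference expression panel with sparse cis-genetic control
#'
#' Emulates a multi-tissue reference panel (genotyped individuals with
#' per-tissue expression): each gene gets `snps_per_gene` independent cis-SNPs
#' with minor-allele frequencies drawn from `maf_range` and dosages drawn as
#' Binomial(2, maf). A fixed fraction `prop_regulated` of gene-tissue pairs is
#' genetically regulated: `n_causal_snps` cis-SNPs get nonzero weights, the
#' genetic value is the weighted dosage sum, and Gaussian noise is scaled so
#' the genetic fraction of expression variance equals `h2`. The remaining
#' pairs are standard-normal noise, giving downstream eQTL filters true
#' negatives. Genes are placed 3 Mb apart on one chromosome so cis windows
#' never overlap.
#'
#' @param config A [sim_config()].
#' @return A list with components `panel` (a `reference_panel`: `genotypes`
#'   [genotype_matrix()], `expression` — named list of tissue matrices,
#'   individuals x genes —, `genes` table, `tissues`) and `truth` (a
#'   `synthetic_truth`: sparse `weights` table, `regulated` pair table,
#'   planted `signature`, `genetic_ref` individuals x pair matrix, the
#'   variant table with true MAFs, and the config).
#' @examples
#' sim <- simulate_reference_panel(sim_config(n_ref = 40, n_genes = 3,
#'                                            n_tissues = 2, snps_per_gene = 8,
#'                                            n_causal_snps = 2, seed = 4))
#' dim(sim$panel$genotypes)
#' @export
simulate_reference_panel <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "reference"))

  genes <- tibble::tibble(
    gene_id = sprintf("G%03d", seq_len(config$n_genes)),
    chrom = "1",
    start = 3e6 * seq_len(config$n_genes),
    end = 3e6 * seq_len(config$n_genes) + 5e4
  )
  tissues <- sprintf("tissue%02d", seq_len(config$n_tissues))

  bases <- c("A", "C", "G", "T")
  variants <- purrr::map_dfr(seq_len(config$n_genes), function(g) {
    k <- config$snps_per_gene
    pos <- sort(sample(seq(genes$start[g] - 5e5, genes$end[g] + 5e5), k))
    alle <- t(replicate(k, sample(bases, 2)))
    tibble::tibble(
      id = sprintf("%s_snp%03d", genes$gene_id[g], seq_len(k)),
      chrom = "1", pos = pos, ref = alle[, 1], alt = alle[, 2],
      gene_id = genes$gene_id[g],
      maf = runif(k, config$maf_range[1], config$maf_range[2])
    )
  })

  n <- config$n_ref
  dos <- vapply(variants$maf, function(m) rbinom(n, 2, m), numeric(n))
  ids <- sprintf("ref%04d", seq_len(n))
  G <- genotype_matrix(dos, variants[, c("id", "chrom", "pos", "ref", "alt")],
                       ids)

  # fixed-count random choice of regulated pairs; planted pairs always regulated
  pairs <- tidyr::expand_grid(gene_id = genes$gene_id, tissue = tissues)
  n_reg <- round(config$prop_regulated * nrow(pairs))
  reg_idx <- sample(nrow(pairs), n_reg)
  pairs$regulated <- seq_len(nrow(pairs)) %in% reg_idx
  if (!is.null(config$signature_pairs)) {
    sig_key <- feature_key(config$signature_pairs$gene_id,
                           config$signature_pairs$tissue)
    all_key <- feature_key(pairs$gene_id, pairs$tissue)
    if (!all(sig_key %in% all_key))
      stop("planted signature pairs outside the gene-tissue universe")
    pairs$regulated[all_key %in% sig_key] <- TRUE
  }

  weights <- list()
  genetic <- matrix(0, n, nrow(pairs),
                    dimnames = list(ids, feature_key(pairs$gene_id, pairs$tissue)))
  expression <- lapply(tissues, function(t)
    matrix(NA_real_, n, config$n_genes, dimnames = list(ids, genes$gene_id)))
  names(expression) <- tissues

  for (i in seq_len(nrow(pairs))) {
    g <- pairs$gene_id[i]; t <- pairs$tissue[i]
    if (pairs$regulated[i] && config$h2 > 0) {
      snps <- variants$id[variants$gene_id == g]
      causal <- sample(snps, config$n_causal_snps)
      w <- rnorm(config$n_causal_snps)
      gv <- as.vector(G$dosages[, causal, drop = FALSE] %*% w)
      vg <- var(gv)
      noise_sd <- if (config$h2 >= 1) 0 else
        if (vg > 0) sqrt(vg * (1 - config$h2) / config$h2) else 1
      expr <- gv + rnorm(n, 0, noise_sd)
      weights[[length(weights) + 1L]] <- tibble::tibble(
        gene_id = g, tissue = t, variant_id = causal, weight = w)
      genetic[, i] <- gv
    } else {
      expr <- rnorm(n)
    }
    expression[[t]][, g] <- expr
  }

  panel <- structure(list(genotypes = G, expression = expression,
                          genes = genes, tissues = tissues),
                     class = "reference_panel")
  truth <- structure(list(
    weights = if (length(weights)) dplyr::bind_rows(weights) else
      tibble::tibble(gene_id = character(), tissue = character(),
                     variant_id = character(), weight = numeric()),
    regulated = pairs,
    signature = config$signature_pairs,
    genetic_ref = genetic,
    variants = variants,
    genes = genes, tissues = tissues,
    config = config
  ), class = "synthetic_truth")
  list(panel = panel, truth = truth)
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("<reference_panel> %d individuals, %d genes x %d tissues, %d cis-SNPs\n",
              length(x$genotypes$individuals), nrow(x$genes),
              length(x$tissues), nrow(x$genotypes$variants)))
  invisible(x)
}

#' Simulate a patient cohort with planted gene-tissue dose effects
#'
#' Draws cohort genotypes from the reference panel's allele frequencies,
#' restricts them to a random platform subset of `snp_overlap` x all SNPs,
#' plants MCAR missingness at `missing_rate`, draws IWPC covariates from
#' simple independent distributions, and sets each patient's weekly dose to
#' IWPC-predicted dose + sum of planted effects x true (noiseless) genetic
#' expression + Gaussian noise. With `dichotomize = TRUE`, patients with dose
#' in `(dose_low, dose_high]` are removed, mimicking an extreme-dose design.
#'
#' @param config A [sim_config()].
#' @param truth `synthetic_truth` from [simulate_reference_panel()] under a
#'   compatible config.
#' @param cohort_index Integer tag used to split the random stream so several
#'   cohorts can be drawn from one panel.
#' @param coefficients IWPC coefficient table (see [read_dose_coefficients()]);
#'   default is the shipped published algorithm.
#' @return A list: `genotypes` ([genotype_matrix()], platform subset, with
#'   missingness), `covariates`, `doses` (tibble with `patient_id`,
#'   `observed_dose`, `predicted_dose`, `residual`), and `genetic_values`
#'   (patients x gene-tissue matrix of true genetic expression, before any
#'   dichotomization filtering it shares the returned patients).
#' @export
simulate_cohort <- function(config, truth, cohort_index = 1,
                            coefficients = read_dose_coefficients()) {
  validate_sim_config(config)
  if (!inherits(truth, "synthetic_truth"))
    stop("truth must come from simulate_reference_panel()")
  has_sig <- !is.null(config$signature_pairs) &&
    nrow(config$signature_pairs) > 0
  if (config$snp_overlap == 0 && has_sig)
    stop("snp_overlap = 0 leaves no imputable features for a planted signature")

  set.seed(derive_seed(config$seed, "cohort", cohort_index))
  n <- config$n_cohort
  ids <- sprintf("pat%02d_%04d", cohort_index, seq_len(n))
  variants <- truth$variants
  dos <- vapply(variants$maf, function(m) rbinom(n, 2, m), numeric(n))
  dimnames(dos) <- list(ids, variants$id)

  # true genetic expression of the cohort, from the planted weights
  genetic <- matrix(0, n, ncol(truth$genetic_ref),
                    dimnames = list(ids, colnames(truth$genetic_ref)))
  if (nrow(truth$weights) > 0) {
    for (grp in split(truth$weights,
                      feature_key(truth$weights$gene_id, truth$weights$tissue))) {
      key <- feature_key(grp$gene_id[1], grp$tissue[1])
      genetic[, key] <- dos[, grp$variant_id, drop = FALSE] %*% grp$weight
    }
  }

  covariates <- simulate_covariates(n, ids)
  predicted <- predict_iwpc(covariates, coefficients)
  effect <- numeric(n)
  if (has_sig) {
    keys <- feature_key(config$signature_pairs$gene_id,
                        config$signature_pairs$tissue)
    effect <- as.vector(genetic[, keys, drop = FALSE] %*%
                          config$signature_pairs$effect)
  }
  observed <- predicted + effect + rnorm(n, 0, config$dose_noise_sd)

  keep <- rep(TRUE, n)
  if (config$dichotomize)
    keep <- dichotomize_keep(observed, config$dose_low, config$dose_high)

  # platform subset, then MCAR missingness
  set.seed(derive_seed(config$seed, "platform", cohort_index))
  n_keep_snp <- round(config$snp_overlap * nrow(variants))
  snp_idx <- sort(sample(nrow(variants), n_keep_snp))
  G <- genotype_matrix(dos[keep, snp_idx, drop = FALSE],
                       variants[snp_idx, c("id", "chrom", "pos", "ref", "alt")],
                       ids[keep])
  G <- plant_missingness(G, config$missing_rate,
                         derive_seed(config$seed, "missingness", cohort_index))

  doses <- tibble::tibble(
    patient_id = ids[keep],
    observed_dose = unname(observed[keep]),
    predicted_dose = unname(predicted[keep]),
    residual = unname(observed[keep] - predicted[keep])
  )
  list(genotypes = G,
       covariates = covariates[keep, ],
       doses = doses,
       genetic_values = genetic[keep, , drop = FALSE])
}

simulate_covariates <- function(n, ids) {
  tibble::tibble(
    patient_id = ids,
    age_decades = sample(3:9, n, replace = TRUE),
    height_cm = round(rnorm(n, 170, 10), 1),
    weight_kg = round(rnorm(n, 80, 16), 1),
    vkorc1_class = sample(c("GG", "AG", "AA"), n, TRUE, c(0.4, 0.4, 0.2)),
    cyp2c9_class = sample(
      c("*1/*1", "*1/*2", "*1/*3", "*2/*2", "*2/*3", "*3/*3", "unknown"),
      n, TRUE, c(0.70, 0.12, 0.08, 0.02, 0.02, 0.01, 0.05)),
    race_class = sample(c("white", "asian", "black_or_AA", "missing_or_mixed"),
                        n, TRUE, c(0.6, 0.15, 0.2, 0.05)),
    enzyme_inducer = sample(c("0", "1"), n, TRUE, c(0.95, 0.05)),
    amiodarone = sample(0:1, n, TRUE, c(0.9, 0.1))
  )
}

#' Extreme-dose (dichotomized) cohort retention rule
#'
#' Keeps low-dose (`dose <= low`) and high-dose (`dose > high`) patients and
#' drops the intermediate range `(low, high]`, mirroring an extreme-dose
#' study design (defaults: low 35, high 49 mg/week).
#'
#' @param dose Weekly doses, mg/week.
#' @param low,high Thresholds (`low < high`).
#' @return Logical vector: `TRUE` for retained patients.
#' @export
dichotomize_keep <- function(dose, low = 35, high = 49) {
  stopifnot(low < high)
  dose <= low | dose > high
}

#' Plant missing-completely-at-random genotype calls
#'
#' Sets each dosage entry to `NA` independently with probability `rate`
#' (the warfarin cohorts carried 0.02-1.1% missing calls).
#'
#' @param G A [genotype_matrix()].
#' @param rate Missingness probability in `[0, 1]`.
#' @param seed Integer seed; the operation is deterministic given it.
#' @return A `genotype_matrix` with missingness planted.
#' @export
plant_missingness <- function(G, rate, seed) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) return(G)
  set.seed(seed)
  d <- G$dosages
  d[runif(length(d)) < rate] <- NA_real_
  genotype_matrix(d, G$variants, G$individuals)
}

#' Simulate a feature-level signature-learning dataset
#'
#' Skips the genotype layer: draws an individuals x gene-tissue feature matrix
#' of i.i.d. standard-normal imputed-expression features and a dose that is
#' linear in the first `n_signature` features plus Gaussian noise. Used to
#' study the stability-selection step in isolation.
#'
#' @param n Individuals.
#' @param p Number of gene-tissue features (assigned two alternating tissues).
#' @param n_signature Number of features with planted effects.
#' @param effect Effect size per planted feature (mg/week per expression unit).
#' @param noise_sd Dose noise SD.
#' @param seed Integer seed.
#' @return A list: `features` ([imputed_features()]), `dose` (numeric),
#'   `truth` (tibble of planted pairs and effects).
#' @export
simulate_signature_dataset <- function(n = 200, p = 200, n_signature = 5,
                                       effect = 1, noise_sd = 1, seed = 1) {
  stopifnot(n_signature <= p)
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  feats <- tibble::tibble(
    gene_id = sprintf("G%03d", seq_len(p)),
    tissue = rep(c("tissue01", "tissue02"), length.out = p)
  )
  ids <- sprintf("pat%04d", seq_len(n))
  beta <- rep(effect, length.out = n_signature)
  y <- as.vector(X[, seq_len(n_signature), drop = FALSE] %*% beta) +
    rnorm(n, 0, noise_sd)
  list(
    features = imputed_features(X, feats, ids),
    dose = setNames(y, ids),
    truth = tibble::tibble(gene_id = feats$gene_id[seq_len(n_signature)],
                           tissue = feats$tissue[seq_len(n_signature)],
                           effect = beta)
  )
}
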
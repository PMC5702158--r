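#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator: the size of the
#' reference expression panel and of the patient cohort, the cis-genetic
#' architecture of expression (SNPs per gene, causal SNPs, cis heritability),
#' the genotyping-platform overlap between cohort and reference, the genotype
#' missingness rate, the planted gene-tissue dose effects, and the dose noise.
#'
#' @param n_ref Number of reference-panel individuals.
#' @param n_cohort Number of cohort patients.
#' @param n_genes,n_tissues Feature-universe dimensions.
#' @param snps_per_gene Cis-SNPs simulated per gene.
#' @param n_causal_snps Causal SNPs per genetically regulated gene-tissue pair;
#'   must not exceed `snps_per_gene`.
#' @param h2 Cis heritability of expression for regulated pairs, in `[0, 1]`.
#' @param prop_regulated Fraction of gene-tissue pairs with nonzero true
#'   SNP weights (the rest are pure noise, giving the eQTL-eligibility filter
#'   true negatives to reject).
#' @param maf_range Length-2 numeric, minor-allele-frequency range in `(0, 0.5]`.
#' @param snp_overlap Fraction of reference SNPs measured on the cohort
#'   platform, in `[0, 1]`.
#' @param missing_rate Genotype missingness fraction, in `[0, 0.011]` by
#'   default bounds (the range observed across the warfarin cohorts).
#' @param signature_pairs Data frame with columns `gene_id`, `tissue`,
#'   `effect` (mg/week per expression unit): the planted dose effects.
#'   `NULL` means no planted signature.
#' @param dose_noise_sd Residual dose noise SD, mg/week.
#' @param dichotomize If `TRUE`, keep only patients with weekly dose
#'   `<= dose_low` or `> dose_high` (extreme-dose design of the
#'   exome-sequenced training cohort).
#' @param dose_low,dose_high Dichotomization thresholds, mg/week.
#' @param seed Master seed; all stage seeds derive from it via [derive_seed()].
#' @return A `sim_config` object (a validated named list).
#' @examples
#' cfg <- sim_config(n_ref = 50, n_cohort = 30, n_genes = 4, n_tissues = 2,
#'                   snps_per_gene = 10, seed = 1)
#' @export
sim_config <- function(n_ref = 300,
                       n_cohort = 200,
                       n_genes = 20,
                       n_tissues = 3,
                       snps_per_gene = 50,
                       n_causal_snps = 5,
                       h2 = 0.5,
                       prop_regulated = 0.5,
                       maf_range = c(0.05, 0.5),
                       snp_overlap = 1,
                       missing_rate = 0,
                       signature_pairs = NULL,
                       dose_noise_sd = 4,
                       dichotomize = FALSE,
                       dose_low = 35,
                       dose_high = 49,
                       seed = 1L) {
  cfg <- list(
    n_ref = as.integer(n_ref), n_cohort = as.integer(n_cohort),
    n_genes = as.integer(n_genes), n_tissues = as.integer(n_tissues),
    snps_per_gene = as.integer(snps_per_gene),
    n_causal_snps = as.integer(n_causal_snps),
    h2 = as.numeric(h2), prop_regulated = as.numeric(prop_regulated),
    maf_range = as.numeric(maf_range), snp_overlap = as.numeric(snp_overlap),
    missing_rate = as.numeric(missing_rate),
    signature_pairs = if (is.null(signature_pairs)) NULL else
      tibble::as_tibble(signature_pairs),
    dose_noise_sd = as.numeric(dose_noise_sd),
    dichotomize = isTRUE(dichotomize),
    dose_low = as.numeric(dose_low), dose_high = as.numeric(dose_high),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_ref >= 1, cfg$n_cohort >= 0, cfg$n_genes >= 1,
            cfg$n_tissues >= 1, cfg$snps_per_gene >= 1)
  if (cfg$h2 < 0 || cfg$h2 > 1) stop("h2 must lie in [0, 1]")
  if (cfg$n_causal_snps > cfg$snps_per_gene)
    stop("n_causal_snps must not exceed snps_per_gene")
  if (cfg$prop_regulated < 0 || cfg$prop_regulated > 1)
    stop("prop_regulated must lie in [0, 1]")
  if (length(cfg$maf_range) != 2 || any(cfg$maf_range <= 0) ||
      any(cfg$maf_range > 0.5) || cfg$maf_range[1] > cfg$maf_range[2])
    stop("maf_range must be an increasing pair in (0, 0.5]")
  if (cfg$snp_overlap < 0 || cfg$snp_overlap > 1)
    stop("snp_overlap must lie in [0, 1]")
  if (cfg$missing_rate < 0 || cfg$missing_rate > 1)
    stop("missing_rate must lie in [0, 1]")
  if (!is.null(cfg$signature_pairs)) {
    req <- c("gene_id", "tissue", "effect")
    if (!all(req %in% names(cfg$signature_pairs)))
      stop("signature_pairs needs columns gene_id, tissue, effect")
  }
  if (cfg$dose_noise_sd < 0) stop("dose_noise_sd must be non-negative")
  if (cfg$dose_low >= cfg$dose_high)
    stop("dichotomization thresholds must satisfy low < high")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  reference: %d individuals; cohort: %d patients\n",
              x$n_ref, x$n_cohort))
  cat(sprintf("  features: %d genes x %d tissues; %d cis-SNPs/gene (%d causal, h2 = %g, %g%% regulated)\n",
              x$n_genes, x$n_tissues, x$snps_per_gene, x$n_causal_snps,
              x$h2, 100 * x$prop_regulated))
  cat(sprintf("  platform overlap %g, missing rate %g; dose noise SD %g mg/week\n",
              x$snp_overlap, x$missing_rate, x$dose_noise_sd))
  np <- if (is.null(x$signature_pairs)) 0L else nrow(x$signature_pairs)
  cat(sprintf("  planted signature: %d pair(s); dichotomize: %s; seed %d\n",
              np, x$dichotomize, x$seed))
  invisible(x)
}

#' Read / write a simulation configuration as YAML
#'
#' The YAML file mirrors [sim_config()] field for field; `signature_pairs`
#' is a list of `{gene_id, tissue, effect}` mappings.
#'
#' @param path File path.
#' @return `read_sim_config()` returns a `sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$signature_pairs))
    raw$signature_pairs <- purrr::map_dfr(raw$signature_pairs, tibble::as_tibble)
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @param config A `sim_config` object.
#' @export
write_sim_config <- function(config, path) {
  out <- unclass(config)
  if (!is.null(out$signature_pairs))
    out$signature_pairs <- purrr::transpose(as.list(out$signature_pairs))
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path)
  invisible(path)
}
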
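#' Default four-cohort layout for end-to-end runs
#'
#' Two training and two validation cohorts; one training cohort is
#' dichotomized (extreme doses only) with reduced platform overlap,
#' emulating an exome-sequenced extreme-dose training design alongside
#' genotyped cohorts.
#'
#' @param n_training,n_validation Patients per cohort.
#' @return A tibble with columns `name`, `role`, `n`, `snp_overlap`,
#'   `dichotomize`, `missing_rate`.
#' @export
default_cohort_layout <- function(n_training = 200, n_validation = 200) {
  tibble::tibble(
    name = c("train_extreme", "train_std", "valid_A", "valid_B"),
    role = c("training", "training", "validation", "validation"),
    n = c(round(1.6 * n_training), n_training, n_validation, n_validation),
    snp_overlap = c(0.5, 0.8, 0.8, 0.8),
    dichotomize = c(TRUE, FALSE, FALSE, FALSE),
    missing_rate = c(0.002, 0.011, 0.005, 0.0002)
  )
}

#' Run the full pipeline: simulate, impute, learn, evaluate
#'
#' Orchestrates one end-to-end run on synthetic data: reference-panel
#' simulation, cohort simulation (with platform subsetting and missingness),
#' kNN genotype imputation, harmonization, cis-eQTL eligibility, per-cohort
#' (cohort-specific) and panel-wide (generic) expression-model training,
#' expression imputation, stability-selected signature learning on each
#' training cohort, IWPC residual computation, and evaluation of every
#' signature on every validation cohort against both empirical nulls with
#' FDR control. When `out_dir` is given, all artifacts (TSV/JSON) and a run
#' manifest with file digests are written.
#'
#' @param config A [sim_config()] (its `n_cohort`, `snp_overlap`,
#'   `dichotomize`, `missing_rate` are overridden per cohort by `cohorts`)
#'   or the path to its YAML file.
#' @param cohorts Cohort layout tibble (see [default_cohort_layout()]).
#' @param strategies Imputation strategies to run; subset of
#'   `c("cohort_specific", "generic")`.
#' @param repeats Stability-selection repeats; default 100.
#' @param n_perm Null permutations/draws per evaluation; default 10,000.
#' @param out_dir Optional output directory.
#' @return A `pipeline_run`: panel, truth, per-cohort data and features,
#'   trained models, signatures, `evals`, the FDR `report`, and `manifest`.
#' @export
run_pipeline <- function(config,
                         cohorts = default_cohort_layout(
                           n_training = config$n_cohort,
                           n_validation = config$n_cohort),
                         strategies = c("cohort_specific", "generic"),
                         repeats = 100, n_perm = 10000, out_dir = NULL) {
  if (is.character(config)) config <- read_sim_config(config)
  validate_sim_config(config)
  strategies <- match.arg(strategies, several.ok = TRUE)
  t0 <- Sys.time()
  timings <- list()
  tick <- function(stage, start) {
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), start, units = "secs"))
  }

  s <- Sys.time()
  sim <- simulate_reference_panel(config)
  panel <- sim$panel; truth <- sim$truth
  tick("simulate_reference", s)

  s <- Sys.time()
  records <- eqtl_scan(panel)
  eligible <- eligible_pairs(records)
  tick("eqtl_scan", s)

  generic_db <- NULL
  if ("generic" %in% strategies) {
    s <- Sys.time()
    generic_db <- train_imputation_models(panel, eligible,
                                          seed = derive_seed(config$seed, "cv_folds"))
    tick("train_generic", s)
  }

  s <- Sys.time()
  cohort_data <- purrr::map(seq_len(nrow(cohorts)), function(i) {
    cfg <- config
    cfg$n_cohort <- as.integer(cohorts$n[i])
    cfg$snp_overlap <- cohorts$snp_overlap[i]
    cfg$dichotomize <- cohorts$dichotomize[i]
    cfg$missing_rate <- cohorts$missing_rate[i]
    ch <- simulate_cohort(cfg, truth, cohort_index = i)
    ch$name <- cohorts$name[i]; ch$role <- cohorts$role[i]
    ch$genotypes <- knn_impute(ch$genotypes)
    harm <- harmonize(ch$genotypes, panel$genotypes)
    ch$genotypes <- apply_harmonization(ch$genotypes, harm)
    # recompute IWPC prediction from covariates (pipeline-side, not simulator-side)
    ch$doses$predicted_dose <- unname(predict_iwpc(ch$covariates))
    ch$doses$residual <- ch$doses$observed_dose - ch$doses$predicted_dose
    ch
  })
  names(cohort_data) <- cohorts$name
  tick("simulate_cohorts", s)

  s <- Sys.time()
  models <- list(); features <- list()
  for (i in seq_along(cohort_data)) {
    ch <- cohort_data[[i]]
    if ("cohort_specific" %in% strategies) {
      db <- train_imputation_models(
        panel, eligible, cohort_snps = ch$genotypes$variants$id,
        seed = derive_seed(config$seed, "cv_folds", 1000 + i))
      models[[paste0(ch$name, "/cohort_specific")]] <- db
      features[[paste0(ch$name, "/cohort_specific")]] <-
        impute_expression(db, ch$genotypes)
    }
    if ("generic" %in% strategies)
      features[[paste0(ch$name, "/generic")]] <-
        impute_expression(generic_db, ch$genotypes)
  }
  tick("impute_expression", s)

  s <- Sys.time()
  training <- cohorts$name[cohorts$role == "training"]
  validation <- cohorts$name[cohorts$role == "validation"]
  signatures <- list()
  for (tr in training) for (st in strategies) {
    key <- paste0(tr, "/", st)
    signatures[[key]] <- stability_select(
      features[[key]], cohort_data[[tr]]$doses$observed_dose,
      repeats = repeats, seed = derive_seed(config$seed, "stability"),
      training_cohort = tr, strategy = st)
  }
  tick("learn_signatures", s)

  s <- Sys.time()
  evals <- list()
  for (sig_key in names(signatures)) {
    sig <- signatures[[sig_key]]
    if (nrow(sig$pairs) == 0) next
    for (va in validation) {
      fkey <- paste0(va, "/", sig$strategy)
      evals[[paste0(sig_key, "->", va)]] <- evaluate_signature(
        sig, features[[fkey]], cohort_data[[va]]$doses$residual,
        n_perm = n_perm, seed = derive_seed(config$seed, "null_shuffled"),
        cohort = va)
    }
  }
  report <- if (length(evals)) eval_report(evals) else NULL
  tick("evaluate", s)

  run <- structure(list(
    config = config, cohort_layout = cohorts, panel = panel, truth = truth,
    eqtl_records = records, eligible = eligible, cohorts = cohort_data,
    generic_db = generic_db, models = models, features = features,
    signatures = signatures, evals = evals, report = report
  ), class = "pipeline_run")

  manifest <- list(
    package_version = as.character(utils::packageVersion("dosesig")),
    master_seed = config$seed,
    stage_seeds = list(
      reference = derive_seed(config$seed, "reference"),
      stability = derive_seed(config$seed, "stability"),
      null_shuffled = derive_seed(config$seed, "null_shuffled"),
      null_random = derive_seed(config$seed, "null_random")
    ),
    config = unclass(config)[setdiff(names(unclass(config)), "signature_pairs")],
    n_eligible_pairs = nrow(eligible),
    timings_sec = timings,
    total_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  if (!is.null(out_dir)) {
    manifest$files <- write_pipeline_artifacts(run, out_dir)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run$manifest <- manifest
  run
}

write_pipeline_artifacts <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  add <- function(p) paths[[length(paths) + 1L]] <<- p
  write_sim_config(run$config, file.path(out_dir, "config.yaml"))
  add(file.path(out_dir, "config.yaml"))
  write_genotypes(run$panel$genotypes,
                  file.path(out_dir, "reference_genotypes.tsv"))
  add(file.path(out_dir, "reference_genotypes.tsv"))
  write_gene_table(run$panel$genes, file.path(out_dir, "genes.tsv"))
  add(file.path(out_dir, "genes.tsv"))
  for (t in run$panel$tissues) {
    p <- file.path(out_dir, paste0("expression_", t, ".tsv"))
    write_expression_matrix(run$panel$expression[[t]], p); add(p)
  }
  readr::write_tsv(run$eqtl_records, file.path(out_dir, "eqtl_records.tsv"))
  add(file.path(out_dir, "eqtl_records.tsv"))
  if (!is.null(run$generic_db)) {
    save_weights_db(run$generic_db, file.path(out_dir, "weights_generic.tsv"))
    add(file.path(out_dir, "weights_generic.tsv"))
  }
  for (nm in names(run$cohorts)) {
    ch <- run$cohorts[[nm]]
    p <- file.path(out_dir, paste0("cohort_", nm, "_genotypes.tsv"))
    write_genotypes(ch$genotypes, p); add(p)
    p <- file.path(out_dir, paste0("cohort_", nm, "_covariates.tsv"))
    readr::write_tsv(ch$covariates, p); add(p)
    p <- file.path(out_dir, paste0("cohort_", nm, "_doses.tsv"))
    readr::write_tsv(ch$doses, p); add(p)
  }
  for (nm in names(run$signatures)) {
    p <- file.path(out_dir,
                   paste0("signature_", gsub("/", "_", nm), ".json"))
    write_signature(run$signatures[[nm]], p); add(p)
  }
  for (nm in names(run$features)) {
    p <- file.path(out_dir, paste0("features_", gsub("/", "_", nm), ".tsv"))
    write_imputed_features(run$features[[nm]], p); add(p)
  }
  if (!is.null(run$report)) {
    readr::write_tsv(run$report, file.path(out_dir, "evaluation_report.tsv"))
    add(file.path(out_dir, "evaluation_report.tsv"))
    jsonlite::write_json(run$report, file.path(out_dir, "evaluation_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    add(file.path(out_dir, "evaluation_report.json"))
  }
  paths <- unlist(paths)
  tibble::tibble(file = basename(paths),
                 md5 = unname(tools::md5sum(paths)))
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>\n")
  cat(sprintf("  %d eligible gene-tissue pair(s); cohorts: %s\n",
              nrow(x$eligible), paste(names(x$cohorts), collapse = ", ")))
  cat(sprintf("  signatures: %s\n", paste(names(x$signatures), collapse = ", ")))
  if (!is.null(x$report)) {
    cat("  evaluation report:\n")
    print(x$report)
  }
  invisible(x)
}
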
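#' Cross-validated LASSO of dose on imputed gene-tissue features
#'
#' One repeat of signature learning: regresses weekly dose on the full
#' imputed feature matrix with the L1 path over the fixed grid, selecting the
#' penalty by minimal fivefold CV mean squared error.
#'
#' @param X An [imputed_features()] matrix (or plain numeric matrix with
#'   `"gene|tissue"` column names).
#' @param y Weekly doses (mg/week), aligned with the rows of `X`.
#' @param folds CV folds.
#' @param seed Fold-assignment seed.
#' @return A list: `weights` (named, zeros kept), `intercept`, `lambda`,
#'   `cv_mse`.
#' @export
fit_lasso_cv <- function(X, y, folds = 5, seed = 1) {
  M <- if (inherits(X, "imputed_features")) X$values else as.matrix(X)
  if (nrow(M) != length(y)) stop("rows of X must align with y")
  fit <- cv_lasso(M, y, folds = folds, seed = seed)
  fit[c("weights", "intercept", "lambda", "cv_mse")]
}

#' Stability-selected gene-tissue dose signature
#'
#' Repeats [fit_lasso_cv()] `repeats` times with different random
#' cross-validation partitions (repeat `r` uses seed `seed + r`) and keeps the
#' gene-tissue pairs whose coefficient is nonzero in a strict majority of
#' repeats (`selection frequency > threshold`; 50/100 is excluded, 51/100 is
#' in).
#'
#' @inheritParams fit_lasso_cv
#' @param repeats Number of stability repeats; default 100.
#' @param threshold Selection-frequency threshold (strict); default 0.5.
#' @param training_cohort,strategy Provenance labels stored in the signature.
#' @return A `dose_signature`: `pairs` (tibble `gene_id`, `tissue`,
#'   `selection_freq`, sorted), `frequencies` (all features), plus
#'   provenance (`training_cohort`, `strategy`, `repeats`, `threshold`,
#'   `seed`).
#' @export
stability_select <- function(X, y, repeats = 100, threshold = 0.5, folds = 5,
                             seed = 1, training_cohort = "training",
                             strategy = "cohort_specific") {
  M <- if (inherits(X, "imputed_features")) X$values else as.matrix(X)
  if (nrow(M) != length(y)) stop("rows of X must align with y")
  feats <- if (inherits(X, "imputed_features")) X$features else {
    parts <- strsplit(colnames(M), "|", fixed = TRUE)
    tibble::tibble(gene_id = purrr::map_chr(parts, 1),
                   tissue = purrr::map_chr(parts, 2))
  }
  if (anyNA(M)) stop("NA in predictor matrix")
  if (sd(y) == 0) stop("constant response")
  lambda <- lasso_grid(M, y)
  full <- lasso_path(M, y, lambda)
  counts <- numeric(ncol(M))
  for (r in seq_len(repeats)) {
    fit <- cv_lasso(M, y, folds = folds, seed = seed + r, lambda = lambda,
                    full_path = full)
    counts <- counts + (fit$weights != 0)
  }
  freq <- unname(counts) / repeats
  frequencies <- dplyr::arrange(
    dplyr::mutate(feats, selection_freq = freq),
    .data$gene_id, .data$tissue)
  pairs <- dplyr::filter(frequencies, .data$selection_freq > threshold)
  structure(list(pairs = pairs, frequencies = frequencies,
                 training_cohort = training_cohort, strategy = strategy,
                 repeats = repeats, threshold = threshold, seed = seed),
            class = "dose_signature")
}

#' Construct a signature from a precomputed frequency table
#'
#' Applies the strict-majority rule to externally supplied selection
#' frequencies (useful for reassembling signatures and for testing the rule
#' itself).
#'
#' @param frequencies Tibble with `gene_id`, `tissue`, `selection_freq`.
#' @param threshold Strict selection threshold.
#' @param repeats Number of repeats the frequencies came from.
#' @inheritParams stability_select
#' @return A `dose_signature`.
#' @export
signature_from_frequencies <- function(frequencies, threshold = 0.5,
                                       repeats = 100,
                                       training_cohort = "training",
                                       strategy = "cohort_specific",
                                       seed = NA_integer_) {
  frequencies <- dplyr::arrange(tibble::as_tibble(frequencies),
                                .data$gene_id, .data$tissue)
  pairs <- dplyr::filter(frequencies, .data$selection_freq > threshold)
  structure(list(pairs = pairs, frequencies = frequencies,
                 training_cohort = training_cohort, strategy = strategy,
                 repeats = repeats, threshold = threshold, seed = seed),
            class = "dose_signature")
}

#' @export
print.dose_signature <- function(x, ...) {
  cat(sprintf("<dose_signature> %d pair(s) (freq > %g over %d repeats; %s, %s)\n",
              nrow(x$pairs), x$threshold, x$repeats, x$training_cohort,
              x$strategy))
  if (nrow(x$pairs) > 0) {
    sel <- x$pairs
    for (i in seq_len(min(nrow(sel), 10)))
      cat(sprintf("  %s / %s  (%.2f)\n", sel$gene_id[i], sel$tissue[i],
                  sel$selection_freq[i]))
    if (nrow(sel) > 10) cat("  ...\n")
  }
  invisible(x)
}

#' @export
tidy.dose_signature <- function(x, ...) {
  dplyr::mutate(x$frequencies,
                selected = .data$selection_freq > x$threshold)
}

#' @export
glance.dose_signature <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x$pairs), repeats = x$repeats,
                 threshold = x$threshold,
                 training_cohort = x$training_cohort, strategy = x$strategy,
                 seed = x$seed)
}

#' Save / read a signature as JSON
#'
#' @param signature A `dose_signature`.
#' @param path JSON path.
#' @return `write_signature()` returns `path` invisibly; `read_signature()`
#'   a `dose_signature`.
#' @export
write_signature <- function(signature, path) {
  jsonlite::write_json(list(
    pairs = signature$pairs,
    frequencies = signature$frequencies,
    training_cohort = signature$training_cohort,
    strategy = signature$strategy,
    repeats = signature$repeats,
    threshold = signature$threshold,
    seed = signature$seed
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    pairs = tibble::as_tibble(raw$pairs),
    frequencies = tibble::as_tibble(raw$frequencies),
    training_cohort = raw$training_cohort, strategy = raw$strategy,
    repeats = raw$repeats, threshold = raw$threshold,
    seed = if (is.null(raw$seed)) NA_integer_ else raw$seed
  ), class = "dose_signature")
}
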
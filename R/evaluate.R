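#' In-sample R-squared of residual dose on signature features
#'
#' Ordinary least squares of the IWPC residual dose on all signature
#' gene-tissue features jointly (with intercept), reporting the in-sample
#' coefficient of determination. Collinear columns are dropped
#' (deterministically, by pivoting order) with a warning.
#'
#' @param features An [imputed_features()] matrix restricted to the signature
#'   (see [signature_features()]), or a plain numeric matrix.
#' @param residuals Residual doses aligned with the rows (see
#'   [residual_dose()]).
#' @return R-squared in `[0, 1]`.
#' @export
regress_r2 <- function(features, residuals) {
  X <- if (inherits(features, "imputed_features")) features$values else
    as.matrix(features)
  y <- as.numeric(residuals)
  n <- nrow(X)
  if (length(y) != n) stop("features and residuals are misaligned")
  if (n <= ncol(X) + 1)
    stop("need n > number of signature features + 1")
  fit <- lm.fit(cbind(`(Intercept)` = 1, X), y)
  if (fit$rank < ncol(X) + 1)
    warning("rank-deficient design: ", ncol(X) + 1 - fit$rank,
            " collinear column(s) dropped")
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(0)
  1 - sum(fit$residuals^2) / tss
}

# Orthonormal basis of the column space of [1 X]; R^2 for any y follows as
# (||Q'y||^2 - n*mean(y)^2) / (sum(y^2) - n*mean(y)^2). Used to score
# thousands of permutations without refitting.
r2_basis <- function(X) {
  qrd <- qr(cbind(1, X))
  qr.Q(qrd)[, seq_len(qrd$rank), drop = FALSE]
}

r2_from_basis <- function(Q, Y) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  qty2 <- colSums(crossprod(Q, Y)^2)
  mu <- colMeans(Y)
  tss <- colSums(Y^2) - n * mu^2
  pmin(pmax((qty2 - n * mu^2) / tss, 0), 1)
}

#' Shuffled-dose null distribution of R-squared
#'
#' Permutes the residual doses against the fixed signature features `n_perm`
#' times and records the in-sample R-squared of each permutation: the
#' distribution of apparent fit when dose carries no signal for these
#' features.
#'
#' @inheritParams regress_r2
#' @param n_perm Number of permutations; default 10,000.
#' @param seed Integer seed.
#' @return Numeric vector of `n_perm` null R-squared values.
#' @export
null_shuffled <- function(features, residuals, n_perm = 10000, seed = 1) {
  X <- if (inherits(features, "imputed_features")) features$values else
    as.matrix(features)
  y <- as.numeric(residuals)
  if (nrow(X) != length(y)) stop("features and residuals are misaligned")
  Q <- r2_basis(X)
  set.seed(seed)
  Y <- vapply(seq_len(n_perm), function(i) y[sample.int(length(y))],
              numeric(length(y)))
  r2_from_basis(Q, Y)
}

#' Random-signature null distribution of R-squared
#'
#' Draws `n_draws` feature sets of the signature's size uniformly without
#' replacement from the gene-tissue pairs *not* in the signature and records
#' the R-squared of each against the true residual doses: the distribution of
#' fit achievable by equally sized but unrelated feature sets.
#'
#' @param all_features The full [imputed_features()] matrix.
#' @param signature A `dose_signature` (or tibble with `gene_id`, `tissue`).
#' @param residuals Residual doses aligned with the rows.
#' @param n_draws Number of random signatures; default 10,000.
#' @param seed Integer seed.
#' @return Numeric vector of `n_draws` null R-squared values.
#' @export
null_random_signatures <- function(all_features, signature, residuals,
                                   n_draws = 10000, seed = 1) {
  pairs <- if (inherits(signature, "dose_signature")) signature$pairs else
    tibble::as_tibble(signature)
  sig_keys <- feature_key(pairs$gene_id, pairs$tissue)
  keys <- colnames(all_features$values)
  complement <- setdiff(keys, sig_keys)
  k <- length(sig_keys)
  if (k == 0) stop("empty signature")
  if (length(complement) < k)
    stop("complement smaller than the signature (",
         length(complement), " < ", k, ")")
  y <- as.numeric(residuals)
  set.seed(seed)
  vapply(seq_len(n_draws), function(i) {
    draw <- sample(complement, k)
    Q <- r2_basis(all_features$values[, draw, drop = FALSE])
    r2_from_basis(Q, y)
  }, numeric(1))
}

#' Empirical p-value against a null distribution
#'
#' Add-one estimator `p = (1 + #\{null >= observed\}) / (1 + N)`: never
#' exactly zero, and `1/(N+1)` at best, matching the resolution of an
#' N-permutation null.
#'
#' @param observed Observed statistic (scalar).
#' @param null_vector Null statistics.
#' @return p-value in `(0, 1]`.
#' @export
empirical_p <- function(observed, null_vector) {
  if (length(null_vector) == 0) stop("empty null vector")
  (1 + sum(null_vector >= observed)) / (1 + length(null_vector))
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up adjusted q-values and the rejection set at level `alpha`.
#'
#' @param p_values Numeric p-values in `[0, 1]`.
#' @param alpha FDR level; default 0.05.
#' @return A list: `q_values`, `rejected` (logical).
#' @export
fdr_bh <- function(p_values, alpha = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  q <- p.adjust(p_values, method = "BH")
  list(q_values = q, rejected = q <= alpha)
}

#' Restrict a feature matrix to a signature's pairs
#'
#' @param X An [imputed_features()] matrix.
#' @param signature A `dose_signature` or tibble with `gene_id`, `tissue`.
#' @return An `imputed_features` with only the signature's columns.
#' @export
signature_features <- function(X, signature) {
  pairs <- if (inherits(signature, "dose_signature")) signature$pairs else
    tibble::as_tibble(signature)
  keys <- feature_key(pairs$gene_id, pairs$tissue)
  missing <- setdiff(keys, colnames(X$values))
  if (length(missing))
    stop("signature pair(s) absent from features: ",
         paste(head(missing, 3), collapse = ", "))
  imputed_features(X$values[, keys, drop = FALSE],
                   pairs[, c("gene_id", "tissue")], X$individuals)
}

#' Evaluate a signature on a validation cohort
#'
#' Computes the in-sample R-squared of residual dose on the signature
#' features, then situates it against the shuffled-dose null and the
#' random-signature null, with add-one empirical p-values.
#'
#' @param signature A `dose_signature`.
#' @param features Full [imputed_features()] matrix of the validation cohort.
#' @param residuals Residual doses ([residual_dose()]) aligned with rows.
#' @param n_perm Permutations / random draws per null; default 10,000.
#' @param seed Integer seed (split internally between the two nulls).
#' @param cohort Validation-cohort label.
#' @return A `signature_eval`: `r2`, `null_shuffled`, `null_random`,
#'   `p_shuffled`, `p_random`, labels and sizes.
#' @export
evaluate_signature <- function(signature, features, residuals,
                               n_perm = 10000, seed = 1,
                               cohort = "validation") {
  sigX <- signature_features(features, signature)
  r2 <- regress_r2(sigX, residuals)
  ns <- null_shuffled(sigX, residuals, n_perm = n_perm,
                      seed = derive_seed(seed, "null_shuffled"))
  nr <- tryCatch(
    null_random_signatures(features, signature, residuals, n_draws = n_perm,
                           seed = derive_seed(seed, "null_random")),
    error = function(e) {
      message("random-signature null unavailable: ", conditionMessage(e))
      NULL
    })
  structure(list(
    signature_label = paste0(signature$training_cohort, "/",
                             signature$strategy),
    cohort = cohort, n = nrow(sigX$values), n_pairs = nrow(signature$pairs),
    r2 = r2, null_shuffled = ns, null_random = nr,
    p_shuffled = empirical_p(r2, ns),
    p_random = if (is.null(nr)) NA_real_ else empirical_p(r2, nr)
  ), class = "signature_eval")
}

#' @export
print.signature_eval <- function(x, ...) {
  cat(sprintf("<signature_eval> %s on %s (n = %d, %d pairs)\n",
              x$signature_label, x$cohort, x$n, x$n_pairs))
  cat(sprintf("  R^2 = %.4f; p = %.3g (random signatures), %.3g (shuffled)\n",
              x$r2, x$p_random, x$p_shuffled))
  invisible(x)
}

#' @export
glance.signature_eval <- function(x, ...) {
  tibble::tibble(signature = x$signature_label, cohort = x$cohort,
                 n = x$n, n_pairs = x$n_pairs, r2 = x$r2,
                 p_random = x$p_random, p_shuffled = x$p_shuffled)
}

#' @export
tidy.signature_eval <- function(x, ...) {
  tibble::tibble(
    null = rep(c("random_signatures", "shuffled"),
               c(length(x$null_random), length(x$null_shuffled))),
    r2 = c(x$null_random, x$null_shuffled)
  )
}

#' Combine evaluations and apply FDR control
#'
#' Collects one row per (signature, validation cohort) evaluation and
#' adjusts each empirical-p family (random-signature and shuffled nulls
#' separately) by Benjamini-Hochberg at level `alpha`.
#'
#' @param evals List of `signature_eval` objects.
#' @param alpha FDR level; default 0.05.
#' @return A tibble with R-squared, both p-values, q-values and rejection
#'   flags per evaluation.
#' @export
eval_report <- function(evals, alpha = 0.05) {
  tab <- purrr::map_dfr(evals, glance)
  adj <- function(p) {
    q <- rep(NA_real_, length(p)); rej <- rep(NA, length(p))
    ok <- !is.na(p)
    if (any(ok)) {
      f <- fdr_bh(p[ok], alpha)
      q[ok] <- f$q_values; rej[ok] <- f$rejected
    }
    list(q = q, rej = rej)
  }
  fr <- adj(tab$p_random)
  fs <- adj(tab$p_shuffled)
  dplyr::mutate(tab,
                q_random = fr$q, sig_random = fr$rej,
                q_shuffled = fs$q, sig_shuffled = fs$rej)
}
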
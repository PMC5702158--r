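# Sparse linear fitting shared by expression-imputation and signature
# learning: one fixed log-spaced lambda grid, fivefold CV by minimal MSE
# (ties -> larger lambda, i.e. the sparser model), refit on all data at the
# chosen lambda. Predictors are used on the raw dosage/expression scale
# (no standardization) so weights read as per-allele / per-unit effects.

#' Fixed regularization grid for the LASSO
#'
#' 100 log-spaced values from `lambda_max` (the smallest penalty that zeroes
#' every coefficient) down to `1e-3 * lambda_max`, under the
#' `(1/2n)||y - b0 - Xb||^2 + lambda ||b||_1` convention.
#'
#' @param x Numeric predictor matrix.
#' @param y Numeric response.
#' @param n_lambda Grid size.
#' @param min_ratio Smallest lambda as a fraction of `lambda_max`.
#' @return Decreasing numeric vector of penalties.
#' @export
lasso_grid <- function(x, y, n_lambda = 100, min_ratio = 1e-3) {
  xc <- scale(x, scale = FALSE)
  lambda_max <- max(abs(crossprod(xc, y - mean(y)))) / length(y)
  if (lambda_max <= 0) lambda_max <- 1e-8
  exp(seq(log(lambda_max), log(min_ratio * lambda_max), length.out = n_lambda))
}

# Full-path fit at the given (decreasing) lambda grid.
# Returns beta (p x n_lambda) and a0 (intercepts). glmnet requires >= 2
# columns; the single-predictor case has a closed-form soft-threshold
# solution and is handled directly.
lasso_path <- function(x, y, lambda) {
  p <- ncol(x)
  if (p == 1) {
    mx <- mean(x); my <- mean(y)
    bx <- x[, 1] - mx; by <- y - my
    n <- length(y)
    rho <- sum(bx * by) / n
    s <- sum(bx^2) / n
    beta <- if (s > 0)
      sign(rho) * pmax(abs(rho) - lambda, 0) / s
    else rep(0, length(lambda))
    beta <- matrix(beta, nrow = 1)
    a0 <- my - beta[1, ] * mx
    rownames(beta) <- colnames(x)
    return(list(beta = beta, a0 = a0, lambda = lambda))
  }
  fit <- glmnet::glmnet(x, y, family = "gaussian", alpha = 1,
                        lambda = lambda, standardize = FALSE,
                        thresh = 1e-5, maxit = 1e6)
  beta <- as.matrix(fit$beta)
  # glmnet may stop the path early; pad with the last fitted model
  if (ncol(beta) < length(lambda)) {
    pad <- length(lambda) - ncol(beta)
    beta <- cbind(beta, beta[, rep(ncol(beta), pad), drop = FALSE])
    a0 <- c(fit$a0, rep(fit$a0[length(fit$a0)], pad))
  } else {
    a0 <- fit$a0
  }
  list(beta = beta, a0 = unname(a0), lambda = lambda)
}

#' Cross-validated LASSO on the fixed grid
#'
#' Assigns individuals to `folds` folds (deterministically from `seed`), fits
#' the full path on each training split, selects the penalty with minimal
#' mean CV squared error — ties resolved toward the larger penalty — and
#' refits on all rows at that penalty.
#'
#' @param x Predictor matrix (rows = individuals).
#' @param y Numeric response.
#' @param folds Number of CV folds.
#' @param seed Integer seed for the fold assignment.
#' @param lambda Optional explicit penalty grid (decreasing); default
#'   [lasso_grid()] on the full data.
#' @param full_path Optional precomputed full-data path at `lambda` (used by
#'   [stability_select()], whose repeats differ only in fold assignment).
#' @return A list: `weights` (named coefficient vector, zeros kept),
#'   `intercept`, `lambda` (selected), `cv_mse` (its CV error), `cv_curve`
#'   (tibble lambda/mse), `foldid`.
#' @export
cv_lasso <- function(x, y, folds = 5, seed = 1, lambda = NULL,
                     full_path = NULL) {
  n <- nrow(x)
  if (n < folds) stop("need at least as many rows as folds")
  if (anyNA(x)) stop("NA in predictor matrix")
  if (sd(y) == 0) stop("constant response")
  lambda <- lambda %||% lasso_grid(x, y)

  set.seed(seed)
  foldid <- sample(rep(seq_len(folds), length.out = n))
  err <- matrix(NA_real_, folds, length(lambda))
  for (f in seq_len(folds)) {
    tr <- foldid != f
    path <- lasso_path(x[tr, , drop = FALSE], y[tr], lambda)
    pred <- x[!tr, , drop = FALSE] %*% path$beta
    pred <- sweep(pred, 2, path$a0, "+")
    err[f, ] <- colMeans((y[!tr] - pred)^2)
  }
  mse <- colMeans(err)
  best <- which.min(mse)  # grid is decreasing: first minimum = largest lambda

  full <- full_path %||% lasso_path(x, y, lambda)
  # path fits run at a moderate convergence threshold for speed; the
  # returned model is polished to subgradient optimality at its lambda
  polished <- cd_polish(x, y, full$beta[, best], lambda[best])
  weights <- polished$weights
  names(weights) <- colnames(x)
  list(weights = weights, intercept = polished$intercept,
       lambda = lambda[best], cv_mse = mse[best],
       cv_curve = tibble::tibble(lambda = lambda, mse = mse),
       foldid = foldid)
}

# Cyclic coordinate descent to subgradient optimality, warm-started from a
# path solution. Works on the centered profile problem (the intercept is
# profiled out exactly), so the polished fit satisfies the KKT conditions
# of `(1/2n)||y - b0 - Xb||^2 + lambda ||b||_1` to `tol`.
cd_polish <- function(x, y, beta, lambda, tol = 1e-8, max_pass = 10000) {
  n <- nrow(x)
  mx <- colMeans(x); my <- mean(y)
  xc <- sweep(x, 2, mx); yc <- y - my
  s <- colMeans(xc^2)
  beta <- as.numeric(beta)
  beta[s == 0] <- 0
  r <- yc - as.vector(xc %*% beta)
  live <- which(s > 0)
  for (pass in seq_len(max_pass)) {
    g <- as.vector(crossprod(xc, r)) / n
    act <- beta != 0
    viol <- max(c(0, abs(g[!act]) - lambda,
                  if (any(act)) abs(g[act] - lambda * sign(beta[act]))))
    if (viol < tol) break
    for (j in live) {
      z <- sum(xc[, j] * r) / n + s[j] * beta[j]
      bj <- sign(z) * max(abs(z) - lambda, 0) / s[j]
      if (bj != beta[j]) {
        r <- r - xc[, j] * (bj - beta[j])
        beta[j] <- bj
      }
    }
  }
  list(weights = beta, intercept = my - sum(mx * beta))
}

#' Verify LASSO optimality (KKT/subgradient) conditions
#'
#' Independent check that a fitted coefficient vector solves
#' `(1/2n)||y - b0 - Xb||^2 + lambda ||b||_1`: for zero coefficients the
#' gradient must satisfy `|x_j' r / n| <= lambda`, for active coefficients
#' `x_j' r / n = lambda * sign(b_j)`, and the mean residual must vanish
#' (free intercept).
#'
#' @param x,y Data the model was fitted on.
#' @param weights Coefficient vector (length `ncol(x)`).
#' @param intercept Fitted intercept.
#' @param lambda Penalty.
#' @return The maximum violation across all conditions (0 = exact optimum).
#' @export
kkt_violation <- function(x, y, weights, intercept, lambda) {
  n <- length(y)
  r <- y - intercept - as.vector(x %*% weights)
  g <- as.vector(crossprod(x, r)) / n
  active <- weights != 0
  viol_zero <- if (any(!active)) max(abs(g[!active]) - lambda, 0) else 0
  viol_act <- if (any(active)) max(abs(g[active] - lambda * sign(weights[active]))) else 0
  max(viol_zero, viol_act, abs(mean(r)))
}
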